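# Agreement metrics for BP estimates: MAE / ME / RMSE / SD of errors, the
# 1 - MSE-ratio score, Bland-Altman limits of agreement, the ISO 81060-2
# accuracy criterion, and the arterial-elasticity utility.

#' Error report for a set of predictions
#'
#' Computes MAE (mean absolute error), ME (mean error), RMSE, the sample SD
#' of the errors, and `r_score = 1 - MSE_model / MSE_standard`, where
#' `MSE_standard` is the mean squared deviation of the truth from its mean.
#' `r_score` is a coefficient-of-determination-style score, not a Pearson
#' correlation: it equals 1 only at perfect prediction and can be negative.
#'
#' @param estimate Predicted BP, mmHg.
#' @param truth Reference BP, mmHg (same length, >= 2).
#' @param phase,target Optional labels carried into the report.
#' @return One-row tibble of class `bp_error_report` with `mae`, `me`,
#'   `rmse`, `sd`, `r_score`, `n`, `phase`, `target`. For constant truth,
#'   `r_score` is `NA` with a warning.
#' @export
error_report <- function(estimate, truth, phase = NA_character_,
                         target = NA_character_) {
  if (length(estimate) != length(truth)) {
    stop("estimate and truth must have equal length", call. = FALSE)
  }
  n <- length(truth)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  err <- estimate - truth
  mse_std <- mean((truth - mean(truth))^2)
  r_score <- if (mse_std == 0) {
    warning("constant truth: r_score undefined", call. = FALSE)
    NA_real_
  } else {
    1 - mean(err^2) / mse_std
  }
  out <- tibble::tibble(
    mae = mean(abs(err)), me = mean(err),
    rmse = sqrt(mean(err^2)), sd = stats::sd(err),
    r_score = r_score, n = n, phase = phase, target = target
  )
  class(out) <- c("bp_error_report", class(out))
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = est - ref`; limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)`; `within_fraction` is the fraction of
#' differences inside the limits.
#'
#' @param ref Reference measurements, mmHg.
#' @param est Estimates, mmHg (same length, >= 2).
#' @return A `bp_bland_altman` object: `mean_diff`, `loa_low`, `loa_high`,
#'   `within_fraction`, `n`, and the per-pair `data` tibble
#'   (`mean`, `diff`) for plotting.
#' @export
bland_altman <- function(ref, est) {
  if (length(ref) != length(est)) {
    stop("ref and est must have equal length", call. = FALSE)
  }
  if (length(ref) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- est - ref
  m <- mean(d)
  s <- stats::sd(d)
  loa <- c(m - 1.96 * s, m + 1.96 * s)
  structure(
    list(mean_diff = m, loa_low = loa[1], loa_high = loa[2],
         within_fraction = mean(d >= loa[1] & d <= loa[2]),
         n = length(d),
         data = tibble::tibble(mean = (ref + est) / 2, diff = d)),
    class = "bp_bland_altman"
  )
}

#' @export
print.bp_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> mean diff %.3f mmHg, LoA [%.3f, %.3f], %.1f%% within (n = %d)\n",
    x$mean_diff, x$loa_low, x$loa_high, 100 * x$within_fraction, x$n))
  invisible(x)
}

#' ISO 81060-2 accuracy verdict
#'
#' Pass iff `|me| <= 5` mmHg and `sd <= 8` mmHg (bounds inclusive — the
#' standard states its limits as maxima).
#'
#' @param me Mean error, mmHg.
#' @param sd Standard deviation of errors, mmHg (>= 0).
#' @return Logical verdict. Vectorized.
#' @examples
#' iso_check(0.32, 7.76) # TRUE
#' @export
iso_check <- function(me, sd) {
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  abs(me) <= 5 & sd <= 8
}

#' Arterial elasticity from vessel geometry and pulse pressure
#'
#' `E = (3/8) * (1 + 2 * r0 / h0) * dp / (dh / h0)` — the incompressible,
#' isotropic thin-wall estimate linking pulse pressure to the per-cycle
#' wall-thickness variation.
#'
#' @param r0 End-diastolic radius, mm.
#' @param h0 Wall thickness, mm.
#' @param dp Pulse pressure, mmHg.
#' @param dh Wall-thickness variation per cycle, mm (`0 < dh < h0`).
#' @return Elasticity E, mmHg. Vectorized.
#' @examples
#' elasticity(r0 = 10, h0 = 1, dp = 40, dh = 0.05) # 6300
#' @export
elasticity <- function(r0, h0, dp, dh) {
  if (any(r0 <= 0) || any(h0 <= 0) || any(dp <= 0)) {
    stop("domain error: r0, h0, dp must be positive", call. = FALSE)
  }
  if (any(dh <= 0)) stop("domain error: dh must be positive", call. = FALSE)
  if (any(dh >= h0)) stop("domain error: dh must be below h0", call. = FALSE)
  (3 / 8) * (1 + 2 * r0 / h0) * dp / (dh / h0)
}

#' Assemble a per-phase evaluation report
#'
#' Collects, for each phase/target with predictions, the error report,
#' Bland-Altman statistics and ISO verdict, alongside the rejection summary
#' of the quality stage.
#'
#' @param predictions Tibble with columns `phase`, `target`, `estimate`,
#'   `truth` (one row per evaluated window).
#' @param beats Classified beat table (for the rejection summary); optional.
#' @return A `bp_phase_report` list: `errors` (tibble, one row per
#'   phase/target with metrics, ISO verdict and Bland-Altman columns) and
#'   `rejection` (tibble or NULL).
#' @export
phase_report <- function(predictions, beats = NULL) {
  stopifnot(all(c("phase", "target", "estimate", "truth") %in% names(predictions)))
  groups <- dplyr::distinct(predictions, .data$phase, .data$target)
  rows <- purrr::pmap(groups, function(phase, target) {
    p <- predictions[predictions$phase == phase & predictions$target == target, ]
    if (nrow(p) < 2) {
      warning(sprintf("phase %s / %s: fewer than 2 predictions; skipped",
                      phase, target), call. = FALSE)
      return(NULL)
    }
    er <- error_report(p$estimate, p$truth, phase = phase, target = target)
    ba <- bland_altman(p$truth, p$estimate)
    dplyr::mutate(er,
                  iso_pass = iso_check(.data$me, .data$sd),
                  ba_mean_diff = ba$mean_diff,
                  ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high,
                  ba_within_fraction = ba$within_fraction)
  })
  errors <- dplyr::bind_rows(rows)
  rejection <- if (!is.null(beats)) rejection_summary(beats) else NULL
  structure(list(errors = errors, rejection = rejection),
            class = "bp_phase_report")
}

#' @export
print.bp_phase_report <- function(x, ...) {
  cat("<bp_phase_report>\n")
  if (!is.null(x$rejection)) {
    cat("rejection by phase:\n"); print(x$rejection)
  }
  cat("errors:\n")
  print(dplyr::select(x$errors, dplyr::all_of(c("phase", "target", "mae", "me",
                                                "sd", "rmse", "r_score", "iso_pass"))))
  invisible(x)
}
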