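# Fiducial detection and the 17-feature morphology vector.
#
# Each accepted beat yields: systolic/diastolic peak amplitudes and times,
# the systolic-to-diastolic interval, pulse interval, augmentation index,
# and the second-derivative (SDPPG) a-e wave amplitudes (b..e normalized by
# a) and inter-wave intervals. Amplitudes are measured relative to the beat
# foot value. A Z-score normalizer (train-set mean/SD) completes the module.

#' Smoothed second derivative of a beat
#'
#' Savitzky-Golay polynomial differentiation (order 4, 9-sample window at
#' 125 Hz, window scaled with the sampling rate) yielding the second
#' derivative in signal units per second squared. Exact for polynomials up
#' to the filter order on interior points and accurate to well under 2% for
#' pulse-band sinusoids (<= 5 Hz) at 125 Hz.
#'
#' @param samples Numeric vector, at least 9 samples (at 125 Hz).
#' @param fs Sampling rate, Hz.
#' @return Numeric vector, same length as `samples`.
#' @export
second_derivative <- function(samples, fs) {
  w <- as.integer(round(9 * fs / 125))
  if (w %% 2 == 0) w <- w + 1L
  w <- max(w, 5L)
  if (length(samples) < w) {
    stop(sprintf("beat too short for second derivative: %d < %d samples",
                 length(samples), w), call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(samples, p = 4, n = w, m = 2, ts = 1 / fs))
}

local_extrema <- function(x, exclude_edge = 2L) {
  n <- length(x)
  if (n < 2 * exclude_edge + 3) return(tibble::tibble(idx = integer(0), type = character(0)))
  core <- (exclude_edge + 1L):(n - exclude_edge)
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- 1  # treat flats as rising so plateaus yield single extrema
  turn <- diff(s)
  max_i <- which(turn < 0) + 1L
  min_i <- which(turn > 0) + 1L
  idx <- c(max_i, min_i)
  type <- c(rep("max", length(max_i)), rep("min", length(min_i)))
  keep <- idx %in% core
  o <- order(idx[keep])
  tibble::tibble(idx = idx[keep][o], type = type[keep][o])
}

#' Detect PPG and SDPPG fiducial points in one beat
#'
#' The systolic peak is the beat's global maximum; the diastolic (reflected)
#' peak is the largest local maximum after the dicrotic region (the first
#' local minimum following the systolic peak). When exercise attenuates the
#' second peak into a shoulder and no local maximum exists, the e-wave time
#' of the second derivative is used as a surrogate and flagged. SDPPG waves
#' a-e are the first five alternating extrema of the smoothed second
#' derivative after the foot, starting with the first maximum.
#'
#' @param samples One beat's PPG samples (foot-to-foot).
#' @param fs Sampling rate, Hz.
#' @return A list of class `ppg_fiducials`: `ok` plus (on success) `t1`,
#'   `sys_amp`, `dia_t`, `dia_amp`, `dia_fallback`, `wave_t` and `wave_amp`
#'   (named a-e; amplitudes are SDPPG values), `foot_value`. On failure,
#'   `ok = FALSE` with a `reason`.
#' @export
detect_fiducials <- function(samples, fs) {
  fail <- function(reason) structure(list(ok = FALSE, reason = reason),
                                     class = "ppg_fiducials")
  n <- length(samples)
  if (n < 9) return(fail("beat too short"))
  v0 <- samples[1]
  sys_idx <- which.max(samples)
  if (sys_idx <= 1 || sys_idx >= n) return(fail("systolic peak at beat boundary"))
  t1 <- (sys_idx - 1) / fs
  sys_amp <- samples[sys_idx] - v0

  d2 <- tryCatch(second_derivative(samples, fs), error = function(e) NULL)
  if (is.null(d2)) return(fail("beat too short for second derivative"))
  ex <- local_extrema(d2)
  ex <- ex[ex$idx > 1, ]
  first_max <- which(ex$type == "max")[1]
  if (is.na(first_max)) return(fail("no SDPPG maximum found"))
  waves <- integer(0)
  want <- "max"
  for (r in first_max:nrow(ex)) {
    if (ex$type[r] == want) {
      waves <- c(waves, ex$idx[r])
      want <- if (want == "max") "min" else "max"
      if (length(waves) == 5) break
    }
  }
  if (length(waves) < 5) return(fail("fewer than 5 qualifying SDPPG extrema"))
  wave_t <- (waves - 1) / fs
  wave_amp <- d2[waves]
  names(wave_t) <- names(wave_amp) <- c("a", "b", "c", "d", "e")
  if (!(all(diff(wave_t) > 0))) return(fail("SDPPG wave ordering violated"))
  if (!(wave_amp[["a"]] > 0)) return(fail("a-wave amplitude not positive"))
  if (!(wave_amp[["b"]] < 0)) return(fail("b-wave amplitude not negative"))

  # diastolic peak after the dicrotic region
  dia_fallback <- FALSE
  after <- samples[(sys_idx + 1):n]
  ex_ppg <- local_extrema(samples, exclude_edge = 1L)
  mins_after <- ex_ppg$idx[ex_ppg$type == "min" & ex_ppg$idx > sys_idx]
  dia_idx <- NA_integer_
  if (length(mins_after) > 0) {
    notch <- mins_after[1]
    maxs_after <- ex_ppg$idx[ex_ppg$type == "max" & ex_ppg$idx > notch]
    if (length(maxs_after) > 0) {
      dia_idx <- maxs_after[which.max(samples[maxs_after])]
    }
  }
  if (is.na(dia_idx)) {
    # attenuated second peak: fall back to the e-wave time
    dia_fallback <- TRUE
    dia_idx <- waves[5]
  }
  dia_t <- (dia_idx - 1) / fs
  dia_amp <- samples[dia_idx] - v0
  if (!(t1 > 0 && t1 < dia_t && dia_t < n / fs)) {
    return(fail("peak ordering violated (t1 < diastolic time < beat length)"))
  }
  structure(
    list(ok = TRUE, t1 = t1, sys_amp = sys_amp,
         dia_t = dia_t, dia_amp = dia_amp, dia_fallback = dia_fallback,
         wave_t = wave_t, wave_amp = wave_amp, foot_value = v0),
    class = "ppg_fiducials"
  )
}

#' Compute the 17-feature vector for one beat
#'
#' @param samples One beat's PPG samples.
#' @param fs Sampling rate, Hz.
#' @param fid A successful [detect_fiducials()] result.
#' @param sbp_ref,dbp_ref Reference BP for the beat, mmHg.
#' @return One-row tibble with the 17 features of [feature_names()] plus
#'   `sbp_ref`, `dbp_ref`, `dia_fallback`.
#' @export
extract_features <- function(samples, fs, fid, sbp_ref = NA_real_, dbp_ref = NA_real_) {
  if (!isTRUE(fid$ok)) stop("cannot extract features from failed fiducials", call. = FALSE)
  wt <- fid$wave_t; wa <- fid$wave_amp
  tibble::tibble(
    f01_systolic_peak = fid$sys_amp,
    f02_diastolic_peak = fid$dia_amp,
    f03_t1 = fid$t1,
    f04_delta_t = fid$dia_t - fid$t1,
    f05_diastolic_peak_time = fid$dia_t,
    f06_pulse_interval = length(samples) / fs,
    f07_augmentation_index = fid$dia_amp / fid$sys_amp,
    f08_a_amp = wa[["a"]],
    f09_b_a = wa[["b"]] / wa[["a"]],
    f10_c_a = wa[["c"]] / wa[["a"]],
    f11_d_a = wa[["d"]] / wa[["a"]],
    f12_e_a = wa[["e"]] / wa[["a"]],
    f13_ta = wt[["a"]],
    f14_tb_a = wt[["b"]] - wt[["a"]],
    f15_tb_c = wt[["c"]] - wt[["b"]],
    f16_tc_d = wt[["d"]] - wt[["c"]],
    f17_td_e = wt[["e"]] - wt[["d"]],
    sbp_ref = sbp_ref, dbp_ref = dbp_ref,
    dia_fallback = fid$dia_fallback
  )
}

#' Extract features for every accepted beat of a recording
#'
#' Runs fiducial detection and feature extraction over the accepted beats of
#' a classified beat table. The beat's reference BP is the median of the
#' step-function reference channels over the beat span. Beats whose fiducial
#' detection fails are excluded; the failures (beat_id, reason) are attached
#' as the `"failures"` attribute and summarized in a message.
#'
#' @param rec A [ppg_recording()] with reference BP channels.
#' @param beats Classified beat table (needs `verdict`).
#' @return Feature tibble (one row per feature-complete accepted beat) with
#'   `beat_id`, `phase`, the 17 features, `sbp_ref`, `dbp_ref`,
#'   `dia_fallback`.
#' @export
extract_beat_features <- function(rec, beats) {
  stopifnot("verdict" %in% names(beats))
  acc <- beats[beats$verdict == "accepted" & !is.na(beats$phase), ]
  fs <- rec$sampling_rate_hz
  has_bp <- all(c("sbp_ref", "dbp_ref") %in% names(rec$data))
  rows <- vector("list", nrow(acc))
  fails <- list()
  for (i in seq_len(nrow(acc))) {
    s <- beat_samples(rec, acc$start_sample[i], acc$end_sample[i])
    fid <- detect_fiducials(s, fs)
    if (!fid$ok) {
      fails[[length(fails) + 1]] <- tibble::tibble(beat_id = acc$beat_id[i],
                                                  reason = fid$reason)
      next
    }
    span <- (acc$start_sample[i] + 1L):acc$end_sample[i]
    sbp <- if (has_bp) stats::median(rec$data$sbp_ref[span]) else NA_real_
    dbp <- if (has_bp) stats::median(rec$data$dbp_ref[span]) else NA_real_
    fv <- extract_features(s, fs, fid, sbp, dbp)
    fv$beat_id <- acc$beat_id[i]
    fv$phase <- acc$phase[i]
    rows[[i]] <- fv
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- out[, c("beat_id", "phase", feature_names(),
                   "sbp_ref", "dbp_ref", "dia_fallback")]
  }
  failures <- dplyr::bind_rows(fails)
  if (nrow(failures) > 0) {
    message(sprintf("fiducial/feature failure on %d of %d accepted beats",
                    nrow(failures), nrow(acc)))
  }
  attr(out, "failures") <- failures
  out
}

#' Fit Z-score normalization statistics
#'
#' Per-feature mean and sample (n-1) standard deviation over a training
#' feature matrix. Features with zero SD are flagged constant and dropped by
#' [zscore_apply()] with a warning.
#'
#' @param data Data frame of numeric feature columns.
#' @param cols Columns to normalize (default: the 17 features present).
#' @return A `zscore_stats` tibble: `feature`, `mean`, `sd`, `constant`,
#'   with attribute `n`.
#' @export
zscore_fit <- function(data, cols = intersect(feature_names(), names(data))) {
  if (nrow(data) < 2) stop("need at least 2 rows to fit normalization", call. = FALSE)
  st <- tibble::tibble(
    feature = cols,
    mean = vapply(cols, function(cl) mean(data[[cl]]), numeric(1)),
    sd = vapply(cols, function(cl) stats::sd(data[[cl]]), numeric(1))
  )
  st$constant <- st$sd == 0 | !is.finite(st$sd)
  if (any(st$constant)) {
    warning(sprintf("constant feature(s) flagged: %s",
                    paste(st$feature[st$constant], collapse = ", ")), call. = FALSE)
  }
  attr(st, "n") <- nrow(data)
  class(st) <- c("zscore_stats", class(st))
  st
}

#' Apply Z-score normalization
#'
#' `(y - M) / SD` element-wise with the training-set statistics — the same
#' statistics must be reused for validation/test data (no leakage). Constant
#' features are dropped with a warning.
#'
#' @param data Data frame containing the fitted feature columns.
#' @param stats A [zscore_fit()] result.
#' @return `data` with normalized feature columns (constants removed).
#' @export
zscore_apply <- function(data, stats) {
  missing_cols <- setdiff(stats$feature, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema mismatch: data lacks %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  drop <- stats$feature[stats$constant]
  if (length(drop) > 0) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(drop, collapse = ", ")), call. = FALSE)
    data <- data[, setdiff(names(data), drop)]
  }
  keep <- stats[!stats$constant, ]
  for (i in seq_len(nrow(keep))) {
    cl <- keep$feature[i]
    data[[cl]] <- (data[[cl]] - keep$mean[i]) / keep$sd[i]
  }
  data
}
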