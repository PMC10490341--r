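# Beat segmentation and skewness-based signal quality screening.
#
# Clean PPG pulses spend most of each cycle near the diastolic baseline with
# a brief systolic excursion, so their sample distribution is right-skewed;
# motion artifacts (baseline wander, slippage dips) destroy that asymmetry.
# The skewness signal quality index (SSQI) is the third standardized moment
# of the beat's samples with population (1/N) normalization.

#' Skewness signal quality index of a PPG segment
#'
#' `SSQI = (1/N) * sum(((x - mean(x)) / sd_pop(x))^3)` where `sd_pop` is the
#' population (1/N) standard deviation.
#'
#' @param samples Numeric vector, at least 3 samples.
#' @return The SSQI (dimensionless); `NA_real_` with a warning for a
#'   degenerate (constant) beat, which callers must reject.
#' @examples
#' compute_ssqi(c(0, 0, 1)) # 1/sqrt(2)
#' @export
compute_ssqi <- function(samples) {
  n <- length(samples)
  if (n < 3) stop("SSQI needs at least 3 samples", call. = FALSE)
  mu <- mean(samples)
  sigma <- sqrt(mean((samples - mu)^2))
  if (sigma == 0) {
    warning("degenerate beat: zero standard deviation; SSQI undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(((samples - mu) / sigma)^3)
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (zero phase lag), used
#' to condition the PPG before upstroke detection. Output length equals
#' input length.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param low_hz,high_hz Pass band edges; `0 < low < high < fs/2`.
#' @param order Butterworth order (per direction).
#' @return Filtered signal.
#' @export
bandpass <- function(x, fs, low_hz = 0.5, high_hz = 8, order = 2) {
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  if (length(x) < 3 * (2 * order + 1)) {
    stop("signal too short for the filter order", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Segment a PPG recording into beats
#'
#' Systolic upstrokes are found by adaptive-threshold peak picking on the
#' first difference of the band-passed PPG (minimum peak distance 0.3 s);
#' each beat foot is the raw-signal minimum in the window preceding its
#' upstroke, and beats span `[foot_i, foot_{i+1})`. Beats shorter than
#' 0.3 s or longer than `max_beat_s` are dropped. The phase label is
#' inherited from the phase containing the foot.
#'
#' @param rec A [ppg_recording()].
#' @param low_hz,high_hz Band-pass edges for the conditioning filter.
#' @param min_beat_s,max_beat_s Allowed beat length bounds, s.
#' @return Tibble with `beat_id`, `start_sample`, `end_sample` (0-based,
#'   half-open), `phase`. Empty (with a warning) if no upstrokes are found.
#' @export
segment_beats <- function(rec, low_hz = 0.5, high_hz = 8,
                          min_beat_s = 0.3, max_beat_s = 2.0) {
  validate_recording(rec)
  fs <- rec$sampling_rate_hz
  x <- rec$data$ppg
  xf <- bandpass(x, fs, low_hz, high_hz)
  dx <- diff(xf)
  # blockwise adaptive threshold: amplitude varies across phases and motion
  # artifacts would otherwise dominate a single global quantile
  block <- max(1L, as.integer(round(10 * fs)))
  mind <- max(1L, as.integer(round(0.3 * fs)))
  up <- integer(0)
  for (b0 in seq(1, length(dx), by = block)) {
    # blocks overlap by one minimum peak distance so no upstroke is lost at
    # a block join
    lo <- max(1L, b0 - mind)
    hi <- min(b0 + block - 1L + mind, length(dx))
    seg <- dx[lo:hi]
    pos <- seg[seg > 0]
    if (length(pos) < 10) next
    thr <- 0.3 * stats::quantile(pos, 0.95, names = FALSE)
    pk <- pracma::findpeaks(seg, minpeakheight = thr, minpeakdistance = mind)
    if (!is.null(pk)) {
      cand <- as.integer(pk[, 2]) + lo - 1L
      up <- c(up, cand[cand >= b0 & cand <= b0 + block - 1L])
    }
  }
  up <- unique(up)
  if (length(up) == 0) {
    warning("no upstrokes found; empty segmentation", call. = FALSE)
    return(empty_beat_table())
  }
  up <- sort(up)
  # enforce the minimum spacing across block joins
  keep <- c(TRUE, diff(up) >= mind)
  while (!all(keep)) {
    up <- up[keep]
    keep <- c(TRUE, diff(up) >= mind)
  }
  w <- as.integer(round(0.30 * fs))
  feet <- vapply(up, function(i) {
    lo <- max(1L, as.integer(i) - w)
    as.integer(lo + which.min(x[lo:as.integer(i)]) - 1L)
  }, integer(1))
  feet <- sort(unique(feet))
  if (length(feet) < 2) {
    warning("fewer than two feet found; empty segmentation", call. = FALSE)
    return(empty_beat_table())
  }
  out <- tibble::tibble(
    start_sample = feet[-length(feet)] - 1L,  # 0-based
    end_sample = feet[-1] - 1L
  )
  len_s <- (out$end_sample - out$start_sample) / fs
  out <- out[len_s >= min_beat_s & len_s <= max_beat_s, ]
  if (nrow(out) == 0) {
    warning("no beats within the length bounds; empty segmentation", call. = FALSE)
    return(empty_beat_table())
  }
  out$beat_id <- seq_len(nrow(out))
  out$phase <- phase_at(rec, out$start_sample)
  out[, c("beat_id", "start_sample", "end_sample", "phase")]
}

empty_beat_table <- function() {
  tibble::tibble(beat_id = integer(0), start_sample = integer(0),
                 end_sample = integer(0), phase = character(0))
}

#' Extract one beat's samples from a recording
#'
#' @param rec A [ppg_recording()].
#' @param start_sample,end_sample 0-based half-open span.
#' @return Numeric vector of PPG samples.
#' @export
beat_samples <- function(rec, start_sample, end_sample) {
  rec$data$ppg[(start_sample + 1L):end_sample]
}

#' Per-beat quality statistics
#'
#' Adds to a beat table the SSQI, beat length in seconds, and peak-to-peak
#' amplitude after per-recording amplitude normalization (division by the
#' median beat peak-to-peak amplitude) — the three statistics the linear-SVM
#' quality mode classifies on.
#'
#' @param rec A [ppg_recording()].
#' @param beats Beat table from [segment_beats()].
#' @return `beats` with `ssqi`, `length_s`, `amplitude` columns added.
#' @export
beat_quality_stats <- function(rec, beats) {
  fs <- rec$sampling_rate_hz
  ssqi <- numeric(nrow(beats))
  amp <- numeric(nrow(beats))
  for (i in seq_len(nrow(beats))) {
    s <- beat_samples(rec, beats$start_sample[i], beats$end_sample[i])
    ssqi[i] <- suppressWarnings(compute_ssqi(s))
    amp[i] <- diff(range(s))
  }
  med <- stats::median(amp[amp > 0])
  if (!is.finite(med) || med == 0) med <- 1
  beats$ssqi <- ssqi
  beats$length_s <- (beats$end_sample - beats$start_sample) / fs
  beats$amplitude <- amp / med
  beats
}

#' Quality model: fixed SSQI threshold or linear SVM
#'
#' @param mode `"threshold"` or `"svm"`.
#' @param threshold SSQI acceptance threshold (threshold mode); a beat is
#'   accepted iff `ssqi >= threshold`. Default 0: clean pulses skew positive.
#' @param svm_fit A fitted linear SVM (svm mode), from
#'   [train_quality_model()].
#' @return A `quality_model` object.
#' @export
quality_model <- function(mode = c("threshold", "svm"), threshold = 0,
                          svm_fit = NULL) {
  mode <- match.arg(mode)
  if (mode == "svm" && is.null(svm_fit)) {
    stop("svm mode requires a trained model; see train_quality_model()", call. = FALSE)
  }
  structure(list(mode = mode, threshold = threshold, svm_fit = svm_fit),
            class = "quality_model")
}

#' Train the linear-SVM quality classifier
#'
#' Fits a linear max-margin classifier on the three per-beat statistics
#' (`ssqi`, `length_s`, `amplitude`) against binary quality labels.
#'
#' @param beats Tibble with the three statistic columns and a `label` column
#'   (factor/character with levels `"clean"` and `"artifact"`), at least 10
#'   beats per class.
#' @return A `quality_model` in svm mode.
#' @export
train_quality_model <- function(beats) {
  stopifnot(all(c("ssqi", "length_s", "amplitude", "label") %in% names(beats)))
  lab <- factor(beats$label, levels = c("clean", "artifact"))
  if (any(is.na(lab))) stop("labels must be 'clean' or 'artifact'", call. = FALSE)
  counts <- table(lab)
  if (length(unique(lab)) < 2) stop("single-class input; need both classes", call. = FALSE)
  if (min(counts) < 10) stop("need at least 10 beats per class", call. = FALSE)
  fit <- e1071::svm(
    x = as.matrix(beats[, c("ssqi", "length_s", "amplitude")]),
    y = lab, kernel = "linear", scale = TRUE
  )
  quality_model(mode = "svm", svm_fit = fit)
}

#' Classify beats as accepted or rejected
#'
#' Threshold mode accepts a beat iff `ssqi >= threshold`; svm mode applies
#' the trained linear decision over (ssqi, beat length, normalized
#' peak-to-peak amplitude). Degenerate beats (undefined SSQI) are always
#' rejected.
#'
#' @param beats Beat table with quality statistics
#'   (see [beat_quality_stats()]).
#' @param model A [quality_model()].
#' @return `beats` with a `verdict` column (`"accepted"`/`"rejected"`).
#' @export
classify_beats <- function(beats, model = quality_model()) {
  stopifnot(inherits(model, "quality_model"))
  if (!("ssqi" %in% names(beats))) {
    stop("beats lack quality statistics; run beat_quality_stats() first", call. = FALSE)
  }
  degenerate <- !is.finite(beats$ssqi)
  if (model$mode == "threshold") {
    acc <- !degenerate & beats$ssqi >= model$threshold
  } else {
    if (is.null(model$svm_fit)) stop("untrained svm quality model", call. = FALSE)
    pred <- stats::predict(
      model$svm_fit,
      as.matrix(beats[, c("ssqi", "length_s", "amplitude")])
    )
    acc <- !degenerate & pred == "clean"
  }
  beats$verdict <- ifelse(acc, "accepted", "rejected")
  beats
}

#' Rejection rate, percent
#'
#' `100 * (1 - n_after / n_before)`, reported to 2 decimals — the arithmetic
#' behind per-phase before/after beat counts.
#'
#' @param n_before,n_after Beat counts before and after quality screening.
#' @return Percentage in `[0, 100]`, rounded to 2 decimals. Vectorized.
#' @examples
#' rejection_rate(14290, 10878) # 23.88
#' @export
rejection_rate <- function(n_before, n_after) {
  if (any(n_before <= 0)) stop("domain error: n_before must be positive", call. = FALSE)
  if (any(n_after < 0) || any(n_after > n_before)) {
    stop("domain error: need 0 <= n_after <= n_before", call. = FALSE)
  }
  round(100 * (1 - n_after / n_before), 2)
}

#' Per-phase rejection summary
#'
#' Tabulates before/after counts and rejection rates by phase from a
#' classified beat table.
#'
#' @param beats Beat table with `phase` and `verdict` columns.
#' @return Tibble with `phase`, `n_before`, `n_after`, `rejection_rate_pct`.
#' @export
rejection_summary <- function(beats) {
  beats |>
    dplyr::filter(!is.na(.data$phase)) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      n_before = dplyr::n(),
      n_after = sum(.data$verdict == "accepted"),
      .groups = "drop"
    ) |>
    dplyr::mutate(rejection_rate_pct = rejection_rate(.data$n_before, .data$n_after)) |>
    dplyr::arrange(match(.data$phase, PHASE_LABELS))
}
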