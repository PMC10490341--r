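#' Construct a PPG recording
#'
#' A `ppg_recording` bundles a uniformly sampled multichannel time series
#' (PPG plus optional beat-to-beat reference blood pressure stored as
#' per-sample step functions) with its protocol phase intervals and free-form
#' subject metadata. Sample indices are 0-based and phase/beat intervals are
#' half-open `[start, end)` throughout the package.
#'
#' @param data Tibble or data frame with columns `time_s`, `ppg` and
#'   optionally `sbp_ref`, `dbp_ref` (mmHg).
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @param phases Tibble with columns `label` (one of `"rest"`, `"exercise"`,
#'   `"recovery"`), `start_sample`, `end_sample` (0-based, half-open).
#' @param subject_meta Named list of subject descriptors (e.g. `age`).
#' @return An object of class `ppg_recording`.
#' @export
ppg_recording <- function(data, sampling_rate_hz, phases, subject_meta = list()) {
  rec <- structure(
    list(
      data = tibble::as_tibble(data),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      phases = tibble::as_tibble(phases),
      subject_meta = subject_meta
    ),
    class = "ppg_recording"
  )
  validate_recording(rec)
  rec
}

PHASE_LABELS <- c("rest", "exercise", "recovery")

#' Validate a PPG recording's invariants
#'
#' Checks channel lengths, the sampling rate, and that phase intervals are
#' within range, ordered and disjoint. Called by every constructor/reader;
#' exported so user-built recordings can be checked too.
#'
#' @param rec A `ppg_recording`.
#' @return `rec`, invisibly. Errors with the violated rule otherwise.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "ppg_recording")) {
    stop("not a ppg_recording object", call. = FALSE)
  }
  if (!is.numeric(rec$sampling_rate_hz) || length(rec$sampling_rate_hz) != 1 ||
      !is.finite(rec$sampling_rate_hz) || rec$sampling_rate_hz <= 0) {
    stop("invariant violated: sampling_rate must be a positive number", call. = FALSE)
  }
  d <- rec$data
  if (!all(c("time_s", "ppg") %in% names(d))) {
    stop("invariant violated: data must contain 'time_s' and 'ppg' columns", call. = FALSE)
  }
  n <- nrow(d)
  ph <- rec$phases
  req <- c("label", "start_sample", "end_sample")
  if (!all(req %in% names(ph))) {
    stop("invariant violated: phases must have label/start_sample/end_sample", call. = FALSE)
  }
  bad <- setdiff(ph$label, PHASE_LABELS)
  if (length(bad) > 0) {
    stop(sprintf("invariant violated: unknown phase label '%s'", bad[[1]]), call. = FALSE)
  }
  if (nrow(ph) > 0) {
    if (any(ph$start_sample < 0) || any(ph$end_sample > n)) {
      stop("invariant violated: phase interval outside [0, n_samples)", call. = FALSE)
    }
    if (any(ph$end_sample <= ph$start_sample)) {
      stop("invariant violated: phase end_sample must exceed start_sample", call. = FALSE)
    }
    if (nrow(ph) > 1 && any(ph$start_sample[-1] < ph$end_sample[-nrow(ph)])) {
      stop("invariant violated: phase intervals must be ordered and disjoint", call. = FALSE)
    }
  }
  invisible(rec)
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf(
    "<ppg_recording> %d samples @ %g Hz (%.1f s), channels: %s\n",
    nrow(x$data), x$sampling_rate_hz, nrow(x$data) / x$sampling_rate_hz,
    paste(setdiff(names(x$data), "time_s"), collapse = ", ")
  ))
  if (nrow(x$phases) > 0) {
    cat("phases:\n")
    print(x$phases)
  }
  invisible(x)
}

#' Number of samples in a recording
#' @param rec A `ppg_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Phase label at each sample
#'
#' @param rec A `ppg_recording`.
#' @param samples 0-based sample indices (default: all samples).
#' @return Character vector of phase labels (`NA` outside any phase).
#' @export
phase_at <- function(rec, samples = seq_len(n_samples(rec)) - 1L) {
  out <- rep(NA_character_, length(samples))
  for (i in seq_len(nrow(rec$phases))) {
    hit <- samples >= rec$phases$start_sample[i] & samples < rec$phases$end_sample[i]
    out[hit] <- rec$phases$label[i]
  }
  out
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a recording from its delimited data file and JSON sidecar
#'
#' The data file is comma-delimited UTF-8 with one header row and columns
#' `time_s`, `ppg` and optionally `sbp_ref`, `dbp_ref`. The sidecar
#' (`<stem>.json`) carries `sampling_rate_hz`, `phases` and `subject_meta`.
#' The time column is checked for uniform spacing consistent with the
#' sampling rate to within 1e-6 s.
#'
#' @param path Path to the data file (sidecar inferred by swapping the
#'   extension for `.json`).
#' @return A validated [ppg_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("format error: data file not found: %s", path), call. = FALSE)
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("format error: missing JSON sidecar: %s", sc), call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz)) {
    stop("format error: sidecar lacks sampling_rate_hz", call. = FALSE)
  }
  fs <- as.numeric(meta$sampling_rate_hz)
  # base read.csv: correctly rounded double parsing, needed for bit-exact
  # round trips of the %.17g representation
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  d <- dplyr::mutate(d, dplyr::across(dplyr::where(is.numeric), as.double))
  if (!all(c("time_s", "ppg") %in% names(d))) {
    stop("format error: data file must have time_s and ppg columns", call. = FALSE)
  }
  expected <- d$time_s[1] + (seq_len(nrow(d)) - 1) / fs
  off <- which(abs(d$time_s - expected) > 1e-6)
  if (length(off) > 0) {
    stop(sprintf(
      "format error: non-uniform time grid at index %d (0-based %d): time %.9f, expected %.9f for %g Hz",
      off[1], off[1] - 1L, d$time_s[off[1]], expected[off[1]], fs
    ), call. = FALSE)
  }
  phases <- tibble::as_tibble(meta$phases)
  if (nrow(phases) > 0) {
    phases$start_sample <- as.integer(phases$start_sample)
    phases$end_sample <- as.integer(phases$end_sample)
  }
  subject_meta <- meta$subject_meta
  if (is.null(subject_meta)) subject_meta <- list()
  ppg_recording(d, fs, phases, as.list(subject_meta))
}

#' Write a recording to a delimited data file plus JSON sidecar
#'
#' Numeric values are written in shortest round-trip representation so that
#' [read_recording()] inverts the write bit-exactly. Absent reference BP
#' channels are simply omitted from the data file and recorded as absent in
#' the sidecar's channel list.
#'
#' @param rec A valid `ppg_recording`.
#' @param path Output path for the data file; the sidecar goes to
#'   `<stem>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  # %.17g guarantees bit-exact double round trips through the text format
  out <- rec$data
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  readr::write_csv(out, path, progress = FALSE, quote = "none")
  meta <- list(
    sampling_rate_hz = rec$sampling_rate_hz,
    channels = setdiff(names(rec$data), "time_s"),
    phases = rec$phases,
    subject_meta = rec$subject_meta
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Canonical 17-feature column names
#'
#' Column order of the per-beat feature table: beat identity, phase, the 17
#' morphological features (systolic/diastolic peak amplitudes and times,
#' pulse interval, augmentation index, SDPPG a-wave amplitude, b/a..e/a
#' ratios and inter-wave intervals), then the beat's reference SBP/DBP.
#'
#' @return Character vector of feature column names (f01..f17).
#' @export
feature_names <- function() {
  c(
    "f01_systolic_peak", "f02_diastolic_peak", "f03_t1", "f04_delta_t",
    "f05_diastolic_peak_time", "f06_pulse_interval", "f07_augmentation_index",
    "f08_a_amp", "f09_b_a", "f10_c_a", "f11_d_a", "f12_e_a",
    "f13_ta", "f14_tb_a", "f15_tb_c", "f16_tc_d", "f17_td_e"
  )
}

feature_table_schema <- function() {
  c("beat_id", "phase", feature_names(), "sbp_ref", "dbp_ref")
}

#' Write a per-beat feature table
#'
#' @param features Tibble with columns `beat_id`, `phase`, the 17 features of
#'   [feature_names()], `sbp_ref` and `dbp_ref`. An empty tibble yields a
#'   header-only file.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  schema <- feature_table_schema()
  missing_cols <- setdiff(schema, names(features))
  if (length(missing_cols) > 0) {
    stop(sprintf("feature table schema mismatch: missing %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  readr::write_csv(features[, schema], path, progress = FALSE)
  invisible(path)
}

#' Read a per-beat feature table
#'
#' @param path CSV path written by [write_feature_table()].
#' @return Tibble in canonical column order.
#' @export
read_feature_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         beat_id = readr::col_integer(),
                         phase = readr::col_character(),
                         .default = readr::col_double()
                       ))
  schema <- feature_table_schema()
  missing_cols <- setdiff(schema, names(d))
  if (length(missing_cols) > 0) {
    stop(sprintf("feature table schema mismatch: missing %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  d[, schema]
}
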