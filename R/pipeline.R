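# End-to-end pipeline: synthesize -> segment/quality -> features ->
# normalize -> RReliefF selection -> windows -> BiLSTM training ->
# evaluation. Every stage writes its artifact to disk and appends a
# JSON-lines audit record so in/out counts are machine-checkable.

pipeline_defaults <- function() {
  list(
    preset = "ci",
    seed = 0L,
    synth = list(n_subjects = 2L, phase_durations_s = c(1200, 1200, 1200),
                 age = 22, resting_hr = 65, intensity = 0.7),
    quality = list(mode = "threshold", threshold = 0),
    selection = list(k = 10, sigma = 50),
    model = list(phases = PHASE_LABELS, targets = c("sbp", "dbp"),
                 window_len = 10, split = c(0.70, 0.15, 0.15),
                 split_mode = "chronological"),
    paths = list(out_dir = NULL)
  )
}

apply_preset <- function(cfg) {
  if (cfg$preset == "ci") {
    cfg$synth$phase_durations_s <- c(240, 240, 600)
    cfg$model$phases <- "recovery"
    cfg$model$targets <- "sbp"
  } else if (cfg$preset != "paper") {
    stop(sprintf("unknown preset '%s' (use 'paper' or 'ci')", cfg$preset), call. = FALSE)
  }
  cfg
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base)) {
      stop(sprintf("unknown config key: %s%s", path, nm), call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], paste0(path, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Build a validated pipeline configuration
#'
#' Starts from the preset (`"ci"`: 2 subjects, 5-min phases, quarter-scale
#' network; `"paper"`: full 20-min phases and full-scale network), applies
#' user overrides, and rejects unknown keys. The configuration round-trips
#' losslessly through JSON.
#'
#' @param ... Named overrides of the default sections (`seed`, `preset`,
#'   `synth`, `quality`, `selection`, `model`, `paths`), or a single `file`
#'   argument naming a JSON config file.
#' @param file Optional JSON config file path.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  user <- list(...)
  if (!is.null(file)) {
    user <- utils::modifyList(jsonlite::read_json(file, simplifyVector = TRUE), user)
  }
  cfg <- pipeline_defaults()
  if (!is.null(user$preset)) cfg$preset <- user$preset
  cfg <- apply_preset(cfg)
  cfg <- merge_config(cfg, user)
  if (abs(sum(cfg$model$split) - 1) > 1e-9 || any(cfg$model$split <= 0)) {
    stop("validation error: model split fractions must be positive and sum to 1",
         call. = FALSE)
  }
  if (cfg$synth$n_subjects < 1) stop("validation error: need >= 1 subject", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

audit_append <- function(log, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  log[[length(log) + 1]] <- rec
  log
}

#' Run the full estimation pipeline
#'
#' Synthesizes `n_subjects` recordings, screens beats with the SSQI quality
#' model, extracts the 17-feature vectors, z-scores them on the training
#' fraction of each phase, scores and masks features with RReliefF
#' (negative scores eliminated), builds sliding windows, trains one
#' BiLSTM model per configured phase and target, and evaluates on the held
#' out eval split. Artifacts (recordings, annotations, features, scores,
#' report, audit log) are written under `out_dir` when given.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A `bp_pipeline_result` list: `report` ([phase_report()]),
#'   `rejection`, `scores`, `models`, `predictions`, `audit`, `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- cfg$paths$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  audit <- list()

  # --- synth + quality + features per subject -----------------------------
  feats_all <- list(); beats_all <- list()
  qmodel <- quality_model(mode = cfg$quality$mode, threshold = cfg$quality$threshold)
  for (s in seq_len(cfg$synth$n_subjects)) {
    pc <- protocol_config(
      phase_durations_s = cfg$synth$phase_durations_s,
      age = cfg$synth$age, resting_hr = cfg$synth$resting_hr,
      intensity = cfg$synth$intensity,
      seed = (cfg$seed * 131L + s) %% 2147483647L
    )
    syn <- synthesize_recording(pc)
    say("subject %d: %d samples, %d beats", s, n_samples(syn$recording), nrow(syn$beats))
    beats <- segment_beats(syn$recording) |>
      beat_quality_stats(rec = syn$recording) |>
      classify_beats(model = qmodel)
    feats <- extract_beat_features(syn$recording, beats)
    if (nrow(feats) > 0) feats$recording_id <- s
    beats$recording_id <- s
    audit <- audit_append(audit, "quality", subject = s,
                          beats_in = nrow(beats),
                          accepted = sum(beats$verdict == "accepted"),
                          rejected = sum(beats$verdict == "rejected"))
    audit <- audit_append(audit, "features", subject = s,
                          beats_in = sum(beats$verdict == "accepted"),
                          feature_rows = nrow(feats),
                          failures = nrow(attr(feats, "failures") %||% tibble::tibble()))
    if (!is.null(out_dir)) {
      write_recording(syn$recording, file.path(out_dir, sprintf("subject%02d.csv", s)))
      readr::write_csv(syn$beats, file.path(out_dir, sprintf("subject%02d_truth.csv", s)))
      readr::write_csv(beats, file.path(out_dir, sprintf("subject%02d_annotations.csv", s)))
    }
    feats_all[[s]] <- feats; beats_all[[s]] <- beats
  }
  features <- dplyr::bind_rows(feats_all)
  beats <- dplyr::bind_rows(beats_all)
  rejection <- rejection_summary(beats)
  if (!is.null(out_dir) && nrow(features) > 0) {
    write_feature_table(features, file.path(out_dir, "features.csv"))
  }

  # --- per phase/target: normalize, select, window, train, evaluate -------
  scores_all <- list(); models <- list(); preds <- list()
  for (ph in cfg$model$phases) {
    fp <- features[features$phase == ph, ]
    fp <- fp[order(fp$recording_id, fp$beat_id), ]
    if (nrow(fp) < 4 * cfg$model$window_len) {
      warning(sprintf("phase %s: too few feature rows (%d); skipped", ph, nrow(fp)),
              call. = FALSE)
      next
    }
    # z-score statistics from the chronological training fraction (no leakage)
    n_tr <- max(2L, floor(cfg$model$split[1] * nrow(fp)))
    st <- suppressWarnings(zscore_fit(fp[seq_len(n_tr), ]))
    fp_z <- suppressWarnings(zscore_apply(fp, st))
    avail <- intersect(feature_names(), names(fp_z))
    for (tg in cfg$model$targets) {
      ycol <- paste0(tg, "_ref")
      sc <- rrelieff(as.matrix(fp_z[seq_len(n_tr), avail]),
                     fp_z[[ycol]][seq_len(n_tr)],
                     k = cfg$selection$k, sigma = cfg$selection$sigma,
                     target = tg, phase = ph)
      kept <- select_nonnegative(sc)
      scores_all[[paste(ph, tg, sep = "_")]] <- sc
      audit <- audit_append(audit, "selection", phase = ph, target = tg,
                            features_in = length(avail), features_kept = length(kept))
      ds <- build_windows(fp_z, window_len = cfg$model$window_len,
                          feature_cols = kept, target = tg)
      if (length(ds$y) < 20) {
        warning(sprintf("phase %s / %s: too few windows (%d); model skipped",
                        ph, tg, length(ds$y)), call. = FALSE)
        next
      }
      parts <- split_dataset(ds, split = cfg$model$split,
                             mode = cfg$model$split_mode, seed = cfg$seed)
      audit <- audit_append(audit, "windows", phase = ph, target = tg,
                            windows = length(ds$y),
                            train = length(parts$train$y),
                            test = length(parts$test$y),
                            eval = length(parts$eval$y))
      mcfg <- bp_model_preset(cfg$preset, seed = cfg$seed)
      say("training %s / %s: %d train windows, %d epochs at scale %g",
          ph, tg, length(parts$train$y),
          max(1L, as.integer(round(mcfg$epochs * mcfg$scale))), mcfg$scale)
      fit <- train_bp_model(parts$train, parts$test, mcfg)
      est <- predict(fit, parts$eval)
      models[[paste(ph, tg, sep = "_")]] <- fit
      preds[[paste(ph, tg, sep = "_")]] <- tibble::tibble(
        phase = ph, target = tg, estimate = est, truth = parts$eval$y,
        baseline = baseline_phase_mean(parts$train, parts$eval)
      )
      audit <- audit_append(audit, "train", phase = ph, target = tg,
                            best_epoch = fit$best_epoch,
                            best_test_mse = fit$best_test_loss)
    }
  }
  predictions <- dplyr::bind_rows(preds)
  report <- if (nrow(predictions) > 0) phase_report(predictions, beats) else NULL

  if (!is.null(out_dir)) {
    if (length(scores_all) > 0) {
      jsonlite::write_json(
        lapply(scores_all, function(s) stats::setNames(as.list(s$weight), s$feature)),
        file.path(out_dir, "scores.json"), auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(report)) {
      jsonlite::write_json(
        list(errors = report$errors, rejection = rejection),
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    }
    writeLines(vapply(audit, function(a) jsonlite::toJSON(a, auto_unbox = TRUE),
                      character(1)),
               file.path(out_dir, "audit.jsonl"))
    manifest <- list(seed = cfg$seed, preset = cfg$preset,
                     package_version = as.character(utils::packageVersion("ppgbp")),
                     r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  structure(
    list(report = report, rejection = rejection, scores = scores_all,
         models = models, predictions = predictions, audit = audit,
         config = cfg, features = features, beats = beats),
    class = "bp_pipeline_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-command end-to-end demonstration
#'
#' Runs [run_pipeline()] on freshly synthesized subjects with the chosen
#' preset and seed.
#'
#' @param seed Integer seed.
#' @param preset `"ci"` (default) or `"paper"`.
#' @param out_dir Optional artifact directory.
#' @param verbose Print progress.
#' @return A `bp_pipeline_result`.
#' @export
demo_pipeline <- function(seed = 0L, preset = "ci", out_dir = NULL, verbose = TRUE) {
  run_pipeline(pipeline_config(preset = preset, seed = seed,
                               paths = list(out_dir = out_dir)),
               verbose = verbose)
}
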