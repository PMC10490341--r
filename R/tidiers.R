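# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained BP model's training curves
#'
#' @param x A `bp_lstm` fit.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `test_loss` (MSE, mmHg^2).
#' @method tidy bp_lstm
#' @export
tidy.bp_lstm <- function(x, ...) {
  x$curves
}

#' One-row summary of a trained BP model
#'
#' @param x A `bp_lstm` fit.
#' @param ... Unused.
#' @return Tibble with target, architecture sizes, parameter count, epochs
#'   run, best epoch and best test MSE.
#' @method glance bp_lstm
#' @export
glance.bp_lstm <- function(x, ...) {
  n_par <- sum(rapply(x$layers, length, how = "unlist"))
  tibble::tibble(
    target = x$target,
    n_features = length(x$features),
    bilstm_units = x$units$bilstm,
    lstm_units = paste(x$units$lstm, collapse = ","),
    n_parameters = n_par,
    epochs_run = x$epochs_run,
    best_epoch = x$best_epoch,
    best_test_mse = x$best_test_loss
  )
}

#' Tidy RReliefF feature scores
#'
#' @param x A `rrelieff_scores` object.
#' @param ... Unused.
#' @return Tibble with `feature`, `weight`, `kept` (non-negative mask).
#' @method tidy rrelieff_scores
#' @export
tidy.rrelieff_scores <- function(x, ...) {
  tibble::tibble(feature = x$feature, weight = x$weight, kept = x$weight >= 0)
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A `bp_bland_altman` object.
#' @param ... Unused.
#' @return One-row tibble with the agreement statistics.
#' @method tidy bp_bland_altman
#' @export
tidy.bp_bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high, within_fraction = x$within_fraction,
                 n = x$n)
}

#' One-row summary of a pipeline run
#'
#' @param x A `bp_pipeline_result`.
#' @param ... Unused.
#' @return Tibble with beat, feature and model counts.
#' @method glance bp_pipeline_result
#' @export
glance.bp_pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_beats = nrow(x$beats),
    n_accepted = sum(x$beats$verdict == "accepted"),
    n_feature_rows = nrow(x$features),
    n_models = length(x$models),
    n_eval_windows = nrow(x$predictions)
  )
}
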