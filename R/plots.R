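# ggplot2 visualizations for recordings, training curves, feature scores
# and Bland-Altman agreement.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PPG recording
#'
#' PPG trace (optionally a time window) with phase boundaries, and the
#' reference BP channels when present.
#'
#' @param object A [ppg_recording()].
#' @param from_s,to_s Optional time window, s.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppg_recording
#' @export
autoplot.ppg_recording <- function(object, from_s = NULL, to_s = NULL, ...) {
  d <- object$data
  if (!is.null(from_s)) d <- d[d$time_s >= from_s, ]
  if (!is.null(to_s)) d <- d[d$time_s <= to_s, ]
  long <- tidyr::pivot_longer(d, -"time_s", names_to = "channel",
                              values_to = "value")
  bounds <- object$phases$start_sample / object$sampling_rate_hz
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (is.null(from_s) && is.null(to_s) && length(bounds) > 1) {
    p <- p + ggplot2::geom_vline(xintercept = bounds[-1], linetype = "dotted")
  }
  p
}

#' Plot training curves of a BP model
#'
#' @param object A `bp_lstm` fit.
#' @param ... Unused.
#' @return A ggplot object with train/test MSE per epoch (log scale).
#' @method autoplot bp_lstm
#' @export
autoplot.bp_lstm <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves, -"epoch",
                              names_to = "split", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = expression(MSE ~ (mmHg^2)),
                  title = sprintf("%s model (best epoch %d)",
                                  toupper(object$target), object$best_epoch))
}

#' Plot RReliefF feature scores
#'
#' @param object A `rrelieff_scores` object.
#' @param ... Unused.
#' @return A ggplot bar chart; eliminated (negative) features highlighted.
#' @method autoplot rrelieff_scores
#' @export
autoplot.rrelieff_scores <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature, .data$weight),
                                  y = .data$weight, fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey30", `FALSE` = "firebrick"),
                               name = "kept") +
    ggplot2::labs(x = NULL, y = "RReliefF weight")
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object: differences against pair means with the mean
#'   difference and 95% limits of agreement.
#' @method autoplot bp_bland_altman
#' @export
autoplot.bp_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean_diff, color = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "mean of reference and estimate (mmHg)",
                  y = "estimate - reference (mmHg)")
}
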