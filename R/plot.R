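# ggplot2 views of the pipeline's objects.

#' Plot a stretch of an ECG record
#'
#' @param record A one-row record tibble.
#' @param window_s Time window in seconds, `c(from, to)`; `NULL` shows the
#'   first 10 seconds.
#' @return A ggplot object.
#' @export
plot_record <- function(record, window_s = NULL) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  sig <- record$signal[[1]]
  t <- (seq_along(sig) - 1) / record$fs
  window_s <- window_s %||% c(0, min(10, record$duration_s))
  keep <- t >= window_s[1] & t <= window_s[2]
  df <- tibble(t = t[keep], mv = sig[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)",
                  title = sprintf("%s (%s, %s)", record$record_id,
                                  record$class_label, record$variant)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_record autoplot method for `ecg_image` objects: renders
#'   the greyscale pixel grid (higher intensity = higher density/magnitude).
#' @param object An `ecg_image`.
#' @param ... Unused.
#' @export
autoplot.ecg_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$intensity <- px[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s, %s)", object$kind,
                                  object$record_id, object$variant),
                  x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot aggregated robustness metrics
#'
#' Mean macro F1 with +/- one standard deviation across folds, grouped by
#' test variant and faceted by transform kind and training variant.
#'
#' @param metrics_summary A [summarize_metrics()] tibble.
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics_summary) {
  ms <- metrics_summary[metrics_summary$class == "macro", ]
  ggplot2::ggplot(ms, ggplot2::aes(x = .data$test_variant, y = .data$mean_f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_f1 - .data$sd_f1,
                                        ymax = .data$mean_f1 + .data$sd_f1),
                           width = 0.25) +
    ggplot2::facet_grid(kind ~ train_variant, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "test dataset", y = "macro F1 (mean ± sd over folds)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_metrics autoplot method for `ecg_classifier`: training
#'   and validation loss per epoch with the early-stopping epoch marked.
#' @param object A fitted `ecg_classifier`.
#' @param ... Unused.
#' @export
autoplot.ecg_classifier <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$stopped_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}
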