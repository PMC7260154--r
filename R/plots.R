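# ggplot2 views of the package's result types.

#' @exportS3Method ggplot2::autoplot
autoplot.vt_sequence <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, -frame, names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = frame, y = value, color = series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = sprintf("size (%s)", object$units),
                  title = "Ground-truth lumen diameter and wall thickness") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.vt_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c(train_mse, val_mse),
                           names_to = "set", values_to = "mse")
  ggplot2::ggplot(h, ggplot2::aes(x = epoch, y = mse, color = set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "MSE (normalized units)",
                  title = "Training history (dotted line: selected epoch)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.vt_metrics <- function(object, ...) {
  p <- dplyr::bind_rows(object$predictions)
  ggplot2::ggplot(p, ggplot2::aes(x = truth, y = estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::facet_wrap(~sequence) +
    ggplot2::labs(x = sprintf("manual / ground truth (%s)", object$units),
                  y = sprintf("estimate (%s)", object$units),
                  title = "Per-frame regression against ground truth") +
    ggplot2::theme_minimal()
}

#' Plot one frame of a sequence
#'
#' @param seq A `vt_sequence`.
#' @param t Frame index (1-based).
#' @return A ggplot raster of the frame with its ground-truth diameter in
#'   the title.
#' @export
plot_frame <- function(seq, t = 1) {
  f <- seq$frames[, , t]
  df <- tibble(row = rep(seq_len(nrow(f)), ncol(f)),
               col = rep(seq_len(ncol(f)), each = nrow(f)),
               intensity = as.vector(f))
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("frame %d, diameter %.2f %s", t - 1,
                                  seq$diameters[t], seq$units)) +
    ggplot2::theme_void()
}
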