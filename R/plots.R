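# ggplot2 views of the main result types.

#' Plot the interaction-score distribution of a screen
#'
#' Histogram of scores with the high-confidence cutoff drawn as a
#' vertical line; the bulk of pairs is expected below 1 (background),
#' with candidate interactions in the right tail.
#'
#' @param object A `spry_screen` score table.
#' @param bins Histogram bin count.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.spry_screen <- function(object, bins = 30, ...) {
  thr <- attr(object, "threshold") %||% 2.5
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "purple") +
    ggplot2::labs(x = "interaction score (OC / EC)", y = "pairs",
                  title = "Interaction-score distribution",
                  subtitle = sprintf("high-confidence cutoff > %g", thr)) +
    ggplot2::theme_minimal()
}

#' Plot a full-length vs SPRY-only concordance histogram
#'
#' @param object A `spry_concordance` from [fullspry_concordance()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.spry_concordance <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = 0.095, fill = "grey35") +
    ggplot2::labs(x = "Spearman rho (full-length vs SPRY-only)",
                  y = "preys", title = "Screen concordance") +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit
#'
#' Observed-contacts points (when the model was fitted from data) with
#' the calibration line.
#'
#' @param object A `spry_calibration`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.spry_calibration <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(object$data))
    p <- p + ggplot2::geom_point(
      data = object$data, ggplot2::aes(x = .data$length, y = .data$oc),
      alpha = 0.6)
  p +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "purple") +
    ggplot2::labs(x = "protein length (residues)",
                  y = "observed contacts (reversed-PAE units)",
                  title = sprintf("EC = %.4g x length + %.6g",
                                  object$slope, object$intercept)) +
    ggplot2::theme_minimal()
}
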