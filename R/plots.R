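# ggplot2 display helpers for the main result types.

raster_df <- function(image) {
  tibble::tibble(
    x = rep(0:(ncol(image) - 1), each = nrow(image)),
    y = rep(0:(nrow(image) - 1), ncol(image)),
    value = as.numeric(image))
}

#' Plot an image with optional detections
#'
#' @param image Numeric matrix (`[y, x]`).
#' @param detections Optional tibble with `x`, `y` columns to overlay.
#' @return A ggplot (y axis reversed so y runs down, as in the images).
#' @export
plot_image <- function(image, detections = NULL) {
  p <- ggplot2::ggplot(raster_df(image), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(fill = "intensity")
  if (!is.null(detections) && nrow(detections) > 0)
    p <- p + ggplot2::geom_point(data = detections, colour = "red",
                                 shape = 3, size = 2)
  p
}

#' Residual plot for a fitted correlation or registration
#'
#' @param x A `clem_correlation` or `affine_registration`.
#' @param ... Unused.
#' @return A ggplot of per-point residuals.
#' @export
autoplot.clem_correlation <- function(x, ...) {
  ggplot2::ggplot(x$residuals, ggplot2::aes(x = .data$id, y = .data$residual_px)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = x$rms, linetype = "dashed") +
    ggplot2::labs(x = "fiducial", y = "residual (px)",
                  title = sprintf("correlation residuals (rms %.3g px)", x$rms)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.clem_correlation
#' @export
autoplot.affine_registration <- function(x, ...) {
  ggplot2::ggplot(x$residuals,
                  ggplot2::aes(x = .data$id, y = .data$residual,
                               fill = .data$inlier)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = x$rms, linetype = "dashed") +
    ggplot2::labs(x = "point pair", y = "residual",
                  title = sprintf("%s registration (rms %.3g, %d/%d inliers)",
                                  x$strategy, x$rms, sum(x$inliers), x$n)) +
    ggplot2::theme_minimal()
}

#' Plot a pattern sequence layout
#'
#' @param seq A [pattern_sequence()].
#' @return A ggplot of the command footprints (um, y down).
#' @export
plot_pattern_sequence <- function(seq) {
  df <- tibble::as_tibble(seq)
  df$order <- factor(seq_len(nrow(df)))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$center_x - .data$width / 2,
      xmax = .data$center_x + .data$width / 2,
      ymin = .data$center_y - .data$height / 2,
      ymax = .data$center_y + .data$height / 2,
      fill = .data$order), alpha = 0.5, colour = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "command") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
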