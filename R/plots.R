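#' Scatter of the first two principal components
#'
#' @param object A [shape_pca()] result.
#' @param colour Optional name of a metadata column to colour points by.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", object$pct[1]),
    y = sprintf("PC2 (%.1f%%)", object$pct[2])
  ) + ggplot2::theme_minimal()
}

#' Histogram of discriminant scores by group
#'
#' @param object A [dfa()] result.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_dfa <- function(object, bins = 25, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(.data$score, fill = .data[[object$group_col]])) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "Discriminant score", y = "Count") +
    ggplot2::theme_minimal()
}

#' Scatter of the first two canonical variates
#'
#' @param object A [cva()] result.
#' @param colour Optional metadata column to colour by.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_cva <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (ncol(object$axes) < 2L) abort("Need at least 2 canonical axes to plot.")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$CV1, .data$CV2))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::labs(
    x = sprintf("CV1 (%.1f%%)", object$pct[1]),
    y = sprintf("CV2 (%.1f%%)", object$pct[2])
  ) + ggplot2::theme_minimal()
}

#' Wireframe comparison plot of two mean shapes
#'
#' @param reference,target `k x 2` shapes.
#' @param links Link list (default [default_wireframe()] for `k = 17`).
#' @param magnification Exaggeration of the target relative to the
#'   reference.
#' @return A ggplot.
#' @export
plot_wireframe <- function(reference, target, links = NULL, magnification = 1) {
  segs <- wireframe_segments(reference, target, links, magnification)
  ggplot2::ggplot(segs, ggplot2::aes(.data$x, .data$y,
                                     xend = .data$xend, yend = .data$yend,
                                     colour = .data$shape,
                                     linetype = .data$shape)) +
    ggplot2::geom_segment(linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  caption = sprintf("target magnified %gx", magnification)) +
    ggplot2::theme_minimal()
}

#' Deformation-grid plot of a thin-plate spline warp
#'
#' @param object A [tps_warp()] result.
#' @param ... Unused.
#' @return A ggplot showing the warped grid with source (open) and target
#'   (filled) landmarks.
#' @export
autoplot.tps_grid <- function(object, ...) {
  g <- object$grid
  lmk <- tibble::tibble(
    x = c(object$source[, 1], object$target[, 1]),
    y = c(object$source[, 2], object$target[, 2]),
    which = rep(c("source", "target"), each = nrow(object$source))
  )
  ggplot2::ggplot() +
    ggplot2::geom_path(data = g, ggplot2::aes(.data$x, .data$y, group = .data$iy),
                       colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_path(data = g, ggplot2::aes(.data$x, .data$y, group = .data$ix),
                       colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = lmk,
                        ggplot2::aes(.data$x, .data$y, shape = .data$which),
                        size = 2) +
    ggplot2::scale_shape_manual(values = c(source = 1, target = 16)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
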