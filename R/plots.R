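#' Plot a shape over a grey image
#'
#' @param image Grey matrix in `[0, 255]` (or `NULL` for shape only).
#' @param shape A shape tibble.
#' @param truth Optional ground-truth shape drawn for comparison.
#' @return A ggplot. The y axis is reversed so the plot matches image
#'   orientation (origin top-left).
#' @export
plot_shape_on_image <- function(image, shape, truth = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    df <- expand.grid(y = seq_len(nrow(image)) - 1, x = seq_len(ncol(image)) - 1)
    df$grey <- as.numeric(image)
    p <- p +
      ggplot2::geom_raster(data = df, ggplot2::aes(.data$x, .data$y, fill = .data$grey)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  close_contour <- function(s) {
    s |>
      dplyr::group_by(.data$vertebra) |>
      dplyr::group_modify(~ dplyr::bind_rows(.x, .x[1, ])) |>
      dplyr::ungroup()
  }
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_path(
      data = close_contour(truth),
      ggplot2::aes(.data$x, .data$y, group = .data$vertebra),
      colour = "cyan", linetype = "22"
    )
  }
  p +
    ggplot2::geom_path(
      data = close_contour(shape),
      ggplot2::aes(.data$x, .data$y, group = .data$vertebra),
      colour = "yellow"
    ) +
    ggplot2::geom_point(
      data = shape, ggplot2::aes(.data$x, .data$y),
      colour = "yellow", size = 0.6
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Mode sweep of a shape model
#'
#' Draws the family of shapes obtained by moving each retained mode weight
#' across its plausible range while the others stay at zero — the standard
#' visualisation of what each principal mode of variation does.
#'
#' @param object A `shape_model`.
#' @param modes Which modes to sweep (default: up to the first 3).
#' @param steps Weight positions per mode, as multiples of the clamp bound
#'   (default `c(-1, -0.5, 0, 0.5, 1)`).
#' @param ... Unused.
#' @return A ggplot faceted by mode.
#' @exportS3Method ggplot2::autoplot
autoplot.shape_model <- function(object, modes = seq_len(min(3, object$t)),
                                 steps = c(-1, -0.5, 0, 0.5, 1), ...) {
  lims <- mode_limits(object)
  sweep <- dplyr::bind_rows(lapply(modes, function(m) {
    dplyr::bind_rows(lapply(steps, function(s) {
      b <- rep(0, object$t)
      b[m] <- s * lims[m]
      sh <- shape_reconstruct(object, b)
      sh <- sh |>
        dplyr::group_by(.data$vertebra) |>
        dplyr::group_modify(~ dplyr::bind_rows(.x, .x[1, ])) |>
        dplyr::ungroup()
      dplyr::mutate(sh, mode = paste("mode", m), step = s)
    }))
  }))
  ggplot2::ggplot(sweep, ggplot2::aes(.data$x, .data$y,
    group = interaction(.data$vertebra, .data$step),
    colour = .data$step)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(colour = "b / limit") +
    ggplot2::theme_minimal()
}

#' Per-vertebra error summary of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot of per-landmark point-to-line errors by vertebra.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$landmarks,
    ggplot2::aes(factor(.data$vertebra), .data$point_to_line)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "22") +
    ggplot2::labs(x = "vertebra", y = "point-to-line error (px)") +
    ggplot2::theme_minimal()
}
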