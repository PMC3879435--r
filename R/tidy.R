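#' Broom-style tidiers for fitted objects
#'
#' @param x A `regression_2d3d`, `icc_result` or `comparison_table`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy regression_2d3d
#' @export
tidy.regression_2d3d <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$b, x$a),
                 std.error = s[, 2],
                 statistic = s[, 3],
                 p.value = s[, 4])
}

#' @rdname tidiers
#' @method glance regression_2d3d
#' @export
glance.regression_2d3d <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r.squared = x$r2, nobs = x$n)
}

#' @rdname tidiers
#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(term = c("between_specimen", "between_pose", "residual"),
                 mean_square = c(x$bms, x$jms, x$ems))
}

#' @rdname tidiers
#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, band = x$band, n = x$n, k = x$k,
                 n_dropped = x$n_dropped)
}

#' @rdname tidiers
#' @method tidy comparison_table
#' @export
tidy.comparison_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot a sensitivity sweep
#'
#' Percent error of each 2D parameter against the perturbation angle, one
#' panel per parameter, coloured by rotation axis.
#'
#' @param object A `sensitivity_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensitivity_table
#' @export
autoplot.sensitivity_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$angle, y = .data$pct_error,
                               colour = .data$axis)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "rotation about axis (deg)",
                  y = "2D measurement change (%)",
                  colour = "axis") +
    ggplot2::theme_minimal()
}

#' Display a DRR as a radiograph-style image
#'
#' @param object A `drr_image`.
#' @param ... Unused.
#' @return A ggplot object (inverted grey scale, mm axes).
#' @method autoplot drr_image
#' @export
autoplot.drr_image <- function(object, ...) {
  ax <- drr_pixel_axes(object)
  df <- expand.grid(u = ax$u, v = ax$v)
  df$intensity <- as.vector(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (mm)", y = "v (mm)",
                  title = paste(object$view, "DRR")) +
    ggplot2::theme_minimal()
}

#' Plot the 2D-vs-3D comparison with calibration lines
#'
#' @param object A `comparison_table`.
#' @param ... Unused.
#' @return A ggplot of percent error per parameter.
#' @method autoplot comparison_table
#' @export
autoplot.comparison_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$parameter,
                                                      .data$pct_error),
                                   y = .data$pct_error)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "2D vs 3D error of cohort means (%)") +
    ggplot2::theme_minimal()
}
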