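#' Plot a cohort validation
#'
#' Scatter of actual versus predicted change with the identity line; the
#' subtitle reports the Pearson correlation.
#'
#' @param object A `cvo_validation` from [validate_cohort()].
#' @param which `"shortening"` (default) or `"lateralization"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cvo_validation
#' @export
autoplot.cvo_validation <- function(object, which = c("shortening", "lateralization"), ...) {
  which <- match.arg(which)
  xv <- paste0("predicted_", which)
  yv <- paste0("actual_", which)
  lab <- paste("predicted vs actual", which)
  row <- object$correlations[object$correlations$comparison == lab, ]
  sub <- if (is.na(row$r)) "r undefined" else sprintf("r = %.3f, p = %.3g, n = %d", row$r, row$p, row$n)
  ggplot2::ggplot(object$scatter, ggplot2::aes(.data[[xv]], .data[[yv]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("Predicted %s (mm)", which),
      y = sprintf("Actual %s (mm)", which),
      title = sprintf("Rotation model: %s", which),
      subtitle = sub
    ) +
    ggplot2::theme_minimal()
}

#' Map predicted shortening over arc-center placements
#'
#' Fills the `(A, B)` plane of candidate arc-center offsets with the
#' predicted shortening at a fixed varus angle and draws the `s_max`
#' contour: placements right of the contour exceed the shortening budget.
#' Visualizes why the arc center should not sit lateral to the head center.
#'
#' @param theta Varus angle in degrees.
#' @param A_range,B_range Offset ranges to map, mm.
#' @param s_max Budget contour, mm.
#' @param n Grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_shortening_field <- function(theta, A_range = c(-10, 22), B_range = c(0, 22),
                                  s_max = 5, n = 101) {
  grid <- tidyr::expand_grid(
    A = seq(A_range[1], A_range[2], length.out = n),
    B = seq(B_range[1], B_range[2], length.out = n)
  )
  grid$shortening <- predict_shortening(grid$A, grid$B, theta)
  ggplot2::ggplot(grid, ggplot2::aes(.data$A, .data$B)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$shortening)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$shortening),
                          breaks = s_max, colour = "black", linewidth = 0.7) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  midpoint = 0, name = "Shortening (mm)") +
    ggplot2::labs(
      x = "Lateral shift A of arc center (mm)",
      y = "Distal shift B of arc center (mm)",
      title = sprintf("Predicted leg shortening at %.1f deg varus", theta),
      subtitle = sprintf("black contour: %g mm budget", s_max)
    ) +
    ggplot2::theme_minimal()
}
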