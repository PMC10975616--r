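#' Plot mean profiles over distance to crossing
#'
#' @param profiles tibble from `analyze_experiment()$speed_profiles` or
#'   `$rotation_profiles`.
#' @param ylab y-axis label.
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, ylab = "value") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$center, y = .data$mean,
                               colour = factor(.data$angle_deg),
                               linetype = .data$motivation)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "distance to crossing [m]", y = ylab,
                  colour = "angle [deg]", linetype = "motivation") +
    ggplot2::theme_minimal()
}

#' Plot the maximum-rotation amplitude fit
#'
#' Scatter of |gamma_max| against the aperture ratio R with the fitted
#' exponential-plateau curve and the critical ratio.
#'
#' @param points data frame with `R` and `amplitude`.
#' @param fit a `fit_result`.
#' @param cp optional `critical_point`.
#' @return A ggplot object.
#' @export
plot_rotation_fit <- function(points, fit, cp = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  p <- fit$parameters
  curve <- data.frame(R = seq(fit$r_domain[1], fit$r_domain[2], length.out = 200))
  curve$amplitude <- p["a"] * exp(-p["b"] * curve$R) + p["d"]
  gg <- ggplot2::ggplot(points, ggplot2::aes(x = .data$R, y = .data$amplitude)) +
    ggplot2::geom_point(alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_line(data = curve, colour = "blue") +
    ggplot2::labs(x = "R = w / s", y = "|max rotation| [deg]") +
    ggplot2::theme_minimal()
  if (!is.null(cp)) {
    gg <- gg + ggplot2::geom_vline(xintercept = cp$rcrit, linetype = "dashed")
  }
  gg
}
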