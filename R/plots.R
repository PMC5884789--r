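#' Plot an orientation density map
#'
#' Equal-area (cylindrical) projection of the sphere: azimuth against
#' `cos(theta)`, tiles coloured by normalised residence density with 1
#' (uniform) as the midpoint of a diverging scale.
#'
#' @param object A `density_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' part <- equal_area_partition(10)
#' u <- sample_spheroid_directions(spheroid_spec(0.53), 2e4, seed = 1)
#' autoplot(sample_density(u, part))
#' @method autoplot density_map
#' @export
autoplot.density_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    xmin = .data$az_lo, xmax = .data$az_hi,
    ymin = .data$cos_lo, ymax = .data$cos_hi,
    fill = .data$density
  )) +
    ggplot2::geom_rect() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "navy", mid = "white",
                                  high = "firebrick", name = "density\n(1 = uniform)") +
    ggplot2::labs(x = "azimuth (rad)", y = expression(cos~theta),
                  title = "Orientation residence density") +
    ggplot2::theme_minimal()
}

#' Plot a convergence report
#'
#' Running error between the actual and the desired partial gravity
#' factor, on log-log axes.
#'
#' @param object A `convergence_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot convergence_report
#' @export
autoplot.convergence_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$t > 0 & df$error > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$error)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "|actual - desired| (g)",
                  title = "Mean-gravity convergence") +
    ggplot2::theme_minimal()
}

#' Plot the gravity-direction components of a trace
#'
#' @param object A `gravity_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gravity_trace
#' @export
autoplot.gravity_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("ux", "uy", "uz"),
                            names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value, colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (s)", y = "gravity direction component",
                  title = "Gravity vector in the sample frame") +
    ggplot2::theme_minimal()
}

#' Plot the eccentricity-to-mean-gravity map
#'
#' The monotone map from spheroid eccentricity to the delivered mean
#' gravity factor, with the standard Moon/Mars/half-g/three-quarter-g
#' settings marked.
#'
#' @param n Number of curve points.
#' @return A ggplot object.
#' @export
plot_eccentricity_map <- function(n = 200) {
  e <- seq(0, 0.995, length.out = n)
  df <- tibble::tibble(e = e, p = mean_g_from_eccentricity(e))
  marks <- tibble::tibble(p = c(0.17, 0.38, 0.50, 0.75),
                          e = eccentricity_for_mean_g(c(0.17, 0.38, 0.50, 0.75)),
                          label = c("Moon", "Mars", "1/2 g", "3/4 g"))
  ggplot2::ggplot(df, ggplot2::aes(.data$e, .data$p)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = marks, colour = "firebrick") +
    ggplot2::geom_text(data = marks, ggplot2::aes(label = .data$label),
                       vjust = -0.7, size = 3) +
    ggplot2::labs(x = "eccentricity e", y = "mean gravity factor p (g)",
                  title = "Spheroid eccentricity vs delivered partial gravity") +
    ggplot2::theme_minimal()
}
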