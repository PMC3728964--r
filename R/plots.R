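#' Plot vital-rate surfaces of a parameter set
#'
#' One panel per vital rate (survival probability, growth conditional mean,
#' fecundity), rate against log-size with one line per displayed year, so
#' the temporal drift of each rate is visible at a glance.
#'
#' @param object A [kernel_params()] object.
#' @param x Log-size grid.
#' @param t Years to display (default 5 snapshots of 0..100).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kernel_params <- function(object, x = seq(0, 10, length.out = 80),
                                   t = seq(0, 100, by = 25), ...) {
  surf <- vital_rate_surfaces(object, x, t) |>
    tidyr::pivot_longer(c("survival", "growth_mean", "fecundity"),
                        names_to = "rate", values_to = "value")
  ggplot2::ggplot(surf, ggplot2::aes(.data$x, .data$value,
                                     colour = factor(.data$t))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~rate, scales = "free_y") +
    ggplot2::labs(x = "log-size", y = NULL, colour = "year") +
    ggplot2::theme_minimal()
}

#' Plot a simulated trajectory
#'
#' Population density against time, with an optional heat map of the size
#' structure underneath it.
#'
#' @param object An `ipm_trajectory`.
#' @param structures Also show the size-structure heat map (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ipm_trajectory <- function(object, structures = TRUE, ...) {
  if (structures) {
    ggplot2::ggplot(as_tibble(object),
                    ggplot2::aes(.data$time, .data$node,
                                 fill = .data$n_value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "n(x, t)") +
      ggplot2::labs(x = "year", y = "log-size") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(trajectory_densities(object),
                    ggplot2::aes(.data$time, .data$density)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "year", y = "density") +
      ggplot2::theme_minimal()
  }
}

#' Plot a fit against the observed densities
#'
#' Reconstructed density trajectory (line) from the fitted parameters and
#' nuisance scale, with the observed densities (points) overlaid.
#'
#' @param object An `ipm_fit`.
#' @param obs The fitted [observed_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ipm_fit <- function(object, obs, ...) {
  stopifnot(is_observed_series(obs))
  tt <- obs_times(obs)
  trajectory <- simulate_series(object$params, object$mesh, t0 = min(tt),
                                horizon = max(tt) - min(tt),
                                initial_density = object$scale0)
  ggplot2::ggplot(trajectory_densities(trajectory),
                  ggplot2::aes(.data$time, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs$densities, colour = "red") +
    ggplot2::labs(x = "year", y = "density (individuals / area)",
                  title = sprintf("reconstruction at w = %g", object$w)) +
    ggplot2::theme_minimal()
}
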