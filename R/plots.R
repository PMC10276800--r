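#' Plot a kymograph
#'
#' Space-time heat map of one species.
#'
#' @param object A `kymograph`.
#' @param species `"u"` (activator, default) or `"v"` (inhibitor).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kymograph <- function(object, species = c("u", "v"), ...) {
  species <- match.arg(species)
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$t,
                                  fill = .data[[species]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = species) +
    ggplot2::labs(x = "x (membrane position)", y = "t (model time)") +
    ggplot2::coord_cartesian(expand = FALSE)
}

#' Plot a wave profile
#'
#' Activator and inhibitor profiles against the co-moving coordinate.
#'
#' @param object A `wave_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wave_profile <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("phi_u", "phi_v"), names_to = "species",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$xi, y = .data$value,
                                  colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(xi == x - c * t), y = "concentration",
                  subtitle = sprintf("c = %.3f", object$c))
}

#' Plot ensemble event statistics against noise intensity
#'
#' Mean and standard deviation of event count, width, duration and maximum
#' per noise intensity.
#'
#' @param object An `ensemble_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_stats <- function(object, ...) {
  d <- object$summary |>
    tidyr::pivot_longer(-c("sigma", "n_runs"),
                        names_to = c("stat", "quantity"), names_sep = "_",
                        values_to = "value") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sigma, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = expression(sigma), y = NULL)
}

#' Plot the eigenvalue locus along a c1 scan
#'
#' The two Jacobian eigenvalues in the complex plane as `c1` varies.
#'
#' @param scan Tibble from [scan_eigenvalues()].
#' @return A ggplot object.
#' @export
plot_eigen_locus <- function(scan) {
  d <- dplyr::bind_rows(
    tibble(c1 = scan$c1, re = scan$re_lambda1, im = scan$im_lambda1),
    tibble(c1 = scan$c1, re = scan$re_lambda2, im = scan$im_lambda2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$re, y = .data$im,
                                  colour = .data$c1)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_viridis_c(name = expression(c[1])) +
    ggplot2::labs(x = expression(Re(lambda)), y = expression(Im(lambda)))
}
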