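# ggplot2 methods for the package's result types.

#' Plot an occupancy curve
#'
#' @param object An [occupancy()] result.
#' @param cohorts Which curves to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_curve <- function(object,
                                     cohorts = c("female", "male",
                                                 "non_breeder", "chick",
                                                 "adults", "total"),
                                     ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::any_of(cohorts),
                              names_to = "cohort", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$count,
                                     colour = .data$cohort)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day of year (season: 60 = Mar 1)",
                  y = "individuals present",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phenological fit with its predictive band
#'
#' Observed counts, posterior-mean adult/chick/total curves, and the
#' 1-sigma multiplicative predictive band of the fitted series.
#'
#' @param object A `phen_fit`.
#' @param n_draws Posterior draws for the band.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phen_fit <- function(object, n_draws = 100, ...) {
  pr <- predict(object, n_draws = n_draws)
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fit_lo, ymax = .data$fit_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$adults, linetype = "adults")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$chicks, linetype = "chicks")) +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$day, y = .data$count),
                        inherit.aes = FALSE, size = 1.2) +
    ggplot2::labs(x = "day of year (season: 60 = Mar 1)", y = "individuals",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the windchill density relation
#'
#' Observed densities against apparent temperature with the posterior-mean
#' sigmoid.
#'
#' @param object A `windchill_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.windchill_fit <- function(object, ...) {
  p <- windchill_point_params(object)
  dat <- predict_density(object$data, p)
  grid <- tibble::tibble(t_apparent = seq(min(dat$t_apparent) - 5,
                                          max(dat$t_apparent) + 5,
                                          length.out = 200))
  grid$density <- density_from_apparent_temperature(grid$t_apparent, p)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_apparent)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$density), alpha = 0.5) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$density),
                       colour = "red") +
    ggplot2::labs(x = "apparent temperature (deg C)",
                  y = "colony density (animals / m2)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
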