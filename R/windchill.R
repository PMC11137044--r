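#' Windchill-model parameters
#'
#' Parameters of the huddling-density model: meteorological variables combine
#' linearly into an apparent temperature
#' \deqn{T_a = T + c_W W + c_R R + c_H H,}
#' and colony density follows a falling sigmoid of the apparent temperature
#' \deqn{\rho(T_a) = \rho_{max} / (1 + \exp((T_a - T_c)/b_0)),}
#' saturating at the hexagonal packing limit \eqn{\rho_{max}} for very cold
#' apparent temperatures and vanishing for warm ones. `T_c` is the critical
#' (half-maximum-density) apparent temperature and `b_0` the transition
#' steepness.
#'
#' @param c_W Windchill factor, degrees C per (m/s). Typically negative: wind
#'   cools.
#' @param c_R Solar radiation factor, degrees C per (W/m2). Typically
#'   positive: sun warms.
#' @param c_H Humidity factor, degrees C per percent relative humidity.
#' @param T_c Critical apparent temperature, degrees C.
#' @param b_0 Sigmoid steepness, degrees C; must be positive.
#' @param rho_max Saturation density, animals/m2. Fixed by default at the
#'   hexagonal packing limit for 0.3 m circles, 12.8 animals/m2.
#' @return An object of class `windchill_params` (a named list).
#' @examples
#' windchill_params(c_W = -1.2, c_R = 0.015, c_H = -0.03, T_c = -25, b_0 = 6)
#' @export
windchill_params <- function(c_W, c_R, c_H, T_c, b_0,
                             rho_max = hexagonal_packing_density(0.3)) {
  vals <- c(c_W = c_W, c_R = c_R, c_H = c_H, T_c = T_c, b_0 = b_0,
            rho_max = rho_max)
  if (any(!is.finite(vals))) abort("all windchill parameters must be finite.")
  if (b_0 <= 0) abort("`b_0` must be > 0.")
  if (rho_max <= 0) abort("`rho_max` must be > 0.")
  structure(as.list(vals), class = "windchill_params")
}

#' @export
print.windchill_params <- function(x, ...) {
  cat("<windchill_params>\n")
  cat(sprintf("  T_a = T + (%.3g) W + (%.3g) R + (%.3g) H\n", x$c_W, x$c_R, x$c_H))
  cat(sprintf("  rho = %.3g / (1 + exp((T_a - (%.3g)) / %.3g)) animals/m2\n",
              x$rho_max, x$T_c, x$b_0))
  invisible(x)
}

#' Reference windchill parameters
#'
#' A realistic parameter set for the austral spring/summer (September to
#' December) density regime, used as the synthetic-season generator's truth
#' and as a packaged default for density prediction when no site-specific
#' fit is available. Marked synthetic: these are not field-fitted values.
#'
#' @return A [windchill_params()] object.
#' @export
windchill_preset <- function() {
  windchill_params(c_W = -1.2, c_R = 0.015, c_H = -0.03, T_c = -25, b_0 = 6)
}

#' Hexagonal packing density
#'
#' Maximum number of circles of a given diameter per unit area under
#' hexagonal close packing: the packing fraction \eqn{\pi/(2\sqrt{3})}
#' divided by the circle area, reported to 3 significant figures. For 0.3 m
#' circles (a huddling adult's footprint) this gives the saturation colony
#' density of 12.8 animals/m2.
#'
#' @param diameter Circle diameter in metres.
#' @return Packing density in animals/m2 (3 significant figures).
#' @examples
#' hexagonal_packing_density(0.3) # 12.8
#' @export
hexagonal_packing_density <- function(diameter) {
  if (!is.numeric(diameter) || any(diameter <= 0)) {
    abort("`diameter` must be positive.")
  }
  signif((pi / (2 * sqrt(3))) / (pi * (diameter / 2)^2), 3)
}

# vectorised numeric core of Eq. T_a
t_apparent_num <- function(temp_c, wind_ms, rad_wm2, rh_pct, params) {
  temp_c + params$c_W * wind_ms + params$c_R * rad_wm2 + params$c_H * rh_pct
}

# vectorised numeric core of the density sigmoid
density_num <- function(t_apparent, params) {
  params$rho_max / (1 + exp((t_apparent - params$T_c) / params$b_0))
}

#' Apparent temperature from weather records
#'
#' Adds the apparent (perceived) temperature `t_apparent` to a weather data
#' frame: the linear combination of air temperature, wind speed, solar
#' radiation and relative humidity that drives huddling.
#'
#' @param weather A data frame with columns `temp_c` (degrees C), `wind_ms`
#'   (m/s, >= 0), `rad_wm2` (W/m2, >= 0) and `rh_pct` (percent, 0-100).
#' @param params A [windchill_params()] object.
#' @return The input as a tibble with a `t_apparent` column appended.
#' @examples
#' w <- tibble::tibble(temp_c = -20, wind_ms = 5, rad_wm2 = 100, rh_pct = 60)
#' apparent_temperature(w, windchill_preset())
#' @export
apparent_temperature <- function(weather, params) {
  check_weather_frame(weather)
  stopifnot(inherits(params, "windchill_params"))
  dplyr::mutate(
    tibble::as_tibble(weather),
    t_apparent = t_apparent_num(.data$temp_c, .data$wind_ms, .data$rad_wm2,
                                .data$rh_pct, params)
  )
}

#' Colony density from apparent temperature
#'
#' The falling sigmoid mapping apparent temperature to expected colony
#' density. Equal to `rho_max / 2` exactly at the critical temperature and
#' strictly decreasing in `t_apparent`.
#'
#' @param t_apparent Apparent temperature(s), degrees C.
#' @param params A [windchill_params()] object.
#' @return Density in animals/m2, in `(0, rho_max)`.
#' @examples
#' p <- windchill_preset()
#' density_from_apparent_temperature(p$T_c, p) # rho_max / 2
#' @export
density_from_apparent_temperature <- function(t_apparent, params) {
  stopifnot(inherits(params, "windchill_params"), is.numeric(t_apparent))
  density_num(t_apparent, params)
}

#' Predict colony density from weather
#'
#' Convenience composition: apparent temperature then the density sigmoid,
#' appended as columns `t_apparent` and `density`.
#'
#' @inheritParams apparent_temperature
#' @return The weather tibble with `t_apparent` and `density` columns.
#' @export
predict_density <- function(weather, params) {
  out <- apparent_temperature(weather, params)
  dplyr::mutate(out, density = density_num(.data$t_apparent, params))
}

#' Individuals from area and density
#'
#' @param area Colony area(s), m2 (>= 0).
#' @param density Colony density(ies), animals/m2 (>= 0).
#' @return Expected number of individuals, `density * area`.
#' @examples
#' counts_from_area(1000, 0.93)
#' @export
counts_from_area <- function(area, density) {
  if (any(area < 0, na.rm = TRUE)) abort("`area` must be >= 0.")
  if (any(density < 0, na.rm = TRUE)) abort("`density` must be >= 0.")
  density * area
}

#' Linearly interpolate counts to query times
#'
#' Counts are observed at irregular (e.g. weekly) dates but needed at image
#' timestamps; values are linearly interpolated between the two nearest
#' available counts. Queries outside the observed span are refused rather
#' than extrapolated.
#'
#' @param counts A data frame with a time column `day` (numeric) or `date`
#'   (`Date`) and a `count` column.
#' @param query_times Numeric days (or `Date`s) at which counts are needed.
#' @return A tibble with columns `day` and `count` at the query times.
#' @examples
#' interpolate_counts(tibble::tibble(day = c(0, 10), count = c(100, 200)), 5)
#' @export
interpolate_counts <- function(counts, query_times) {
  counts <- tibble::as_tibble(counts)
  tcol <- if ("day" %in% names(counts)) "day" else if ("date" %in% names(counts)) "date" else
    abort("`counts` needs a `day` or `date` column.")
  if (!"count" %in% names(counts)) abort("`counts` needs a `count` column.")
  x <- as.numeric(counts[[tcol]])
  q <- as.numeric(query_times)
  if (length(x) < 2) abort("need at least 2 count observations to interpolate.")
  if (any(q < min(x) | q > max(x))) {
    abort(sprintf(
      "query times outside the observed span [%.6g, %.6g]; refusing to extrapolate.",
      min(x), max(x)))
  }
  ord <- order(x)
  yhat <- approx(x[ord], counts$count[ord], xout = q, ties = mean)$y
  tibble::tibble(day = q, count = yhat)
}

#' Average predictions within civil days
#'
#' When several images exist for a single day, per-image predicted counts
#' are averaged into one value per civil day to reduce sampling bias.
#'
#' @param predicted A data frame with a `timestamp` (POSIXct) or `date`
#'   column and a `value` column (or the column named by `col`).
#' @param col Name of the value column to average.
#' @return A tibble with one row per civil day: `date`, averaged `col`, and
#'   `n_obs`.
#' @export
daily_average_counts <- function(predicted, col = "count") {
  predicted <- tibble::as_tibble(predicted)
  if (!col %in% names(predicted)) abort(sprintf("no column `%s` to average.", col))
  if ("timestamp" %in% names(predicted)) {
    predicted$date <- as.Date(predicted$timestamp, tz = "UTC")
  }
  if (!"date" %in% names(predicted)) abort("`predicted` needs a `timestamp` or `date` column.")
  predicted |>
    dplyr::group_by(date = .data$date) |>
    dplyr::summarise("{col}" := mean(.data[[col]]), n_obs = dplyr::n(),
                     .groups = "drop")
}

check_weather_frame <- function(weather) {
  need <- c("temp_c", "wind_ms", "rad_wm2", "rh_pct")
  miss <- setdiff(need, names(weather))
  if (length(miss) > 0) {
    abort(paste0("weather frame is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(weather$wind_ms < 0, na.rm = TRUE)) abort("`wind_ms` must be >= 0.")
  if (any(weather$rad_wm2 < 0, na.rm = TRUE)) abort("`rad_wm2` must be >= 0.")
  if (any(weather$rh_pct < 0 | weather$rh_pct > 100, na.rm = TRUE)) {
    abort("`rh_pct` must be within [0, 100].")
  }
  invisible(weather)
}
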