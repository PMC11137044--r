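# Synthetic colony seasons with known ground truth: weather, counts,
# densities and areas carrying exactly the statistical structure the models
# assume (sinusoidal weather, lognormal count/density noise, areas obtained
# by inverting the windchill model), so every fitting stage can be tested
# end-to-end without field data.

#' Specification of a synthetic season
#'
#' Bundles the ground-truth phenology and windchill parameters, the weather
#' process, the observation schedule and the noise levels for one simulated
#' colony-season.
#'
#' @param phenology True [phenology_params()].
#' @param windchill True [windchill_params()].
#' @param site A [colony_site()] (drives solar radiation and sunrise logic).
#' @param season_year Calendar year of the season start (March 1).
#' @param weather Named list of weather-process settings: `temp_mean`,
#'   `temp_seasonal_amp`, `temp_diurnal_amp`, `temp_sd` (degrees C),
#'   `wind_mean`, `wind_sd` (m/s), `rad_peak` (W/m2 clear-sky at 90 deg
#'   sun), `rad_sd` (lognormal cloudiness sd), `rh_mean`, `rh_sd` (percent).
#' @param count_days Day-of-year observation schedule for counts;
#'   `"weekly"` for every 7 days across the season.
#' @param noise_count Lognormal sd of count observations (0 = exact).
#' @param noise_area Lognormal sd of area measurements (0 = exact).
#' @param seed Integer seed; every generated stream is reproducible from
#'   `(spec, seed)`.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(phenology = phenology_preset("pointe-geologie"),
                           windchill = windchill_preset(),
                           site = colony_site("synthetic-pg",
                                              -(66 + 40 / 60), 140 + 1 / 60),
                           season_year = 2019,
                           weather = list(),
                           count_days = "weekly",
                           noise_count = 0.10,
                           noise_area = 0,
                           seed = 1L) {
  stopifnot(inherits(phenology, "phenology_params"),
            inherits(windchill, "windchill_params"),
            inherits(site, "colony_site"))
  wdef <- list(temp_mean = -9, temp_seasonal_amp = 8, temp_diurnal_amp = 3,
               temp_sd = 3, wind_mean = 6, wind_sd = 3, rad_peak = 900,
               rad_sd = 0.3, rh_mean = 70, rh_sd = 10)
  weather <- utils::modifyList(wdef, weather)
  if (noise_count < 0 || noise_area < 0) abort("noise sds must be >= 0.")
  if (identical(count_days, "weekly")) {
    count_days <- seq(season_start_doy() + 3, season_end_doy(), by = 7)
  }
  if (any(count_days < season_start_doy() | count_days > season_end_doy())) {
    abort("`count_days` must lie within the season (days 60..424).")
  }
  structure(list(phenology = phenology, windchill = windchill, site = site,
                 season_year = season_year, weather = weather,
                 count_days = count_days, noise_count = noise_count,
                 noise_area = noise_area, seed = as.integer(seed)),
            class = "generator_spec")
}

# continuous day-of-year -> POSIXct UTC for the season
doy_to_time <- function(day, season_year) {
  as.POSIXct(sprintf("%d-01-01 00:00:00", season_year), tz = "UTC") +
    (day - 1) * 86400
}

time_to_doy <- function(timestamp, season_year) {
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", season_year), tz = "UTC")
  as.numeric(difftime(timestamp, t0, units = "days")) + 1
}

#' Generate synthetic weather
#'
#' Seasonal and diurnal sinusoids plus Gaussian noise for temperature, wind,
#' and humidity; solar radiation follows the site's solar altitude with
#' lognormal (median-one) cloudiness. All values respect physical bounds
#' (wind and radiation >= 0, humidity in 0..100). Zero noise settings give
#' the pure deterministic curves.
#'
#' @param spec A [generator_spec()].
#' @param days Continuous day-of-year times at which to generate records
#'   (fractions encode time of day, UTC).
#' @return A tibble: `timestamp`, `day`, `temp_c`, `wind_ms`, `rad_wm2`,
#'   `rh_pct`.
#' @export
generate_weather <- function(spec, days) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed + 101L)
  w <- spec$weather
  n <- length(days)
  doy <- ((days - 1) %% 365) + 1
  hour <- (days %% 1) * 24
  temp <- w$temp_mean + w$temp_seasonal_amp * cos(2 * pi * (doy - 15) / 365) +
    w$temp_diurnal_amp * sin(2 * pi * (hour - 9) / 24) +
    rnorm(n, 0, w$temp_sd)
  wind <- pmax(0, w$wind_mean + rnorm(n, 0, w$wind_sd))
  # local solar altitude from declination and hour angle
  decl <- solar_declination(doy)
  hra <- (hour + spec$site$lon_deg / 15 - 12) * 15 * pi / 180
  lat <- spec$site$lat_deg * pi / 180
  sin_alt <- sin(lat) * sin(decl * pi / 180) +
    cos(lat) * cos(decl * pi / 180) * cos(hra)
  cloud <- if (w$rad_sd > 0) exp(rnorm(n, 0, w$rad_sd)) else rep(1, n)
  rad <- pmax(0, w$rad_peak * pmax(sin_alt, 0) * pmin(cloud, 1))
  rh <- pmin(100, pmax(0, w$rh_mean + rnorm(n, 0, w$rh_sd)))
  tibble::tibble(timestamp = doy_to_time(days, spec$season_year), day = days,
                 temp_c = temp, wind_ms = wind, rad_wm2 = rad, rh_pct = rh)
}

#' Generate synthetic counts
#'
#' Samples noisy adult/chick/total counts on the observation schedule from
#' the true occupancy curve with multiplicative lognormal noise (median
#' unbiased), or from the individual-based [agent_oracle()] when
#' `agent_mode = TRUE`. The noiseless truth is attached.
#'
#' @param spec A [generator_spec()].
#' @param agent_mode Draw integer counts from the agent simulation instead
#'   of perturbing the analytic expectation?
#' @return A tibble `day`, `adults`, `chicks`, `total` with attribute
#'   `truth` (the full-resolution [occupancy()] curve).
#' @export
generate_counts <- function(spec, agent_mode = FALSE) {
  stopifnot(inherits(spec, "generator_spec"))
  truth <- occupancy(spec$phenology)
  days <- spec$count_days
  if (agent_mode) {
    sim <- agent_oracle(spec$phenology, n_pairs = round(spec$phenology$BP),
                        seed = spec$seed + 202L, days = days)
    out <- tibble::tibble(day = days, adults = sim$adults, chicks = sim$chick,
                          total = sim$total)
  } else {
    set.seed(spec$seed + 202L)
    exact <- occupancy(spec$phenology, days = days)
    noise <- function(x) x * exp(rnorm(length(x), 0, spec$noise_count))
    out <- tibble::tibble(day = days, adults = noise(exact$adults),
                          chicks = noise(exact$chick))
    out$total <- out$adults + out$chicks
  }
  attr(out, "truth") <- truth
  attr(out, "spec") <- spec
  out
}

#' Generate synthetic colony areas
#'
#' Inverts the windchill model: at each requested time the area is the true
#' total occupancy divided by the density the true windchill parameters
#' predict from the generated weather, `A(t) = N(t) / rho(T_a(t))`, with
#' optional multiplicative noise. Times where the predicted density falls
#' below `density_floor` (an essentially empty colony, where area is
#' undefined) are skipped with a warning.
#'
#' @param spec A [generator_spec()].
#' @param days Continuous day-of-year times of the area measurements.
#' @param weather Optional pre-generated weather at `days` (regenerated from
#'   the spec when omitted).
#' @param density_floor Minimum density (animals/m2) for a usable area.
#' @return A tibble `timestamp`, `day`, `area_m2` with attributes `weather`
#'   and `truth_counts` (the exact `N(t)` at the kept times).
#' @export
generate_areas <- function(spec, days, weather = NULL, density_floor = 1e-3) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(weather)) weather <- generate_weather(spec, days)
  wx <- predict_density(weather, spec$windchill)
  core <- schedule_core(spec$phenology)
  n_true <- rowSums(occupancy_matrix(core, days))
  keep <- wx$density >= density_floor
  if (any(!keep)) {
    warn(sprintf("skipping %d time(s) with predicted density below %.3g animals/m2.",
                 sum(!keep), density_floor))
  }
  area <- n_true[keep] / wx$density[keep]
  if (spec$noise_area > 0) {
    set.seed(spec$seed + 303L)
    area <- area * exp(rnorm(length(area), 0, spec$noise_area))
  }
  out <- tibble::tibble(timestamp = doy_to_time(days[keep], spec$season_year),
                        day = days[keep], area_m2 = area)
  attr(out, "weather") <- weather[keep, ]
  attr(out, "truth_counts") <- n_true[keep]
  out
}

#' Simulate a complete synthetic season
#'
#' Convenience wrapper producing the three observation streams a real
#' campaign would yield: weekly counts, minutely-style weather at the image
#' times, and late-season colony areas (default: two images per day,
#' 04:00 and 13:00 UTC, September through December).
#'
#' @param spec A [generator_spec()].
#' @param area_days Day-of-year times of the simulated images.
#' @return A list with `counts`, `weather`, `areas`, and `truth` (occupancy
#'   curve plus the spec).
#' @export
simulate_season <- function(spec,
                            area_days = rep(seq(244, 365, by = 2), each = 2) +
                              c(4, 13) / 24) {
  counts <- generate_counts(spec)
  weather <- generate_weather(spec, area_days)
  areas <- generate_areas(spec, area_days, weather = weather)
  list(counts = counts, weather = weather, areas = areas,
       truth = list(occupancy = attr(counts, "truth"), spec = spec))
}
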