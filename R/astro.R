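#' Define a colony site
#'
#' A colony site carries the name and geographic coordinates used by the
#' solar-geometry helpers and the satellite-mode fit, where the arrival date
#' is anchored to the first sunrise after midwinter at the site.
#'
#' @param name Site name.
#' @param lat_deg Latitude in decimal degrees, negative south. Antarctic
#'   colonies have `lat_deg <= 0`.
#' @param lon_deg Longitude in decimal degrees, negative west.
#' @return An object of class `colony_site` (a named list).
#' @examples
#' colony_site("Pointe Geologie", -(66 + 40 / 60), 140 + 1 / 60)
#' @export
colony_site <- function(name, lat_deg, lon_deg) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(lat_deg) || length(lat_deg) != 1 || lat_deg < -90 || lat_deg > 90) {
    abort("`lat_deg` must be a single value in [-90, 90].")
  }
  if (lat_deg > 0) {
    abort("`lat_deg` must be <= 0 (southern hemisphere) for colony sites.")
  }
  if (!is.numeric(lon_deg) || length(lon_deg) != 1 || lon_deg < -180 || lon_deg > 180) {
    abort("`lon_deg` must be a single value in [-180, 180].")
  }
  structure(list(name = name, lat_deg = lat_deg, lon_deg = lon_deg),
            class = "colony_site")
}

#' @export
print.colony_site <- function(x, ...) {
  cat(sprintf("<colony_site> %s (%.4f deg lat, %.4f deg lon)\n",
              x$name, x$lat_deg, x$lon_deg))
  invisible(x)
}

#' Solar declination
#'
#' Low-precision solar declination from the standard fraction-of-year Fourier
#' series (Spencer 1971), accurate to a few hundredths of a degree — ample
#' for day-level sunrise logic.
#'
#' @param date A `Date` vector, or a numeric day-of-year (1-based; values
#'   beyond 365 wrap into the next year).
#' @param hour_utc Hour of day (UTC, decimal) at which to evaluate; defaults
#'   to 12.
#' @return Declination in degrees, in `[-23.45, 23.45]`.
#' @examples
#' solar_declination(as.Date("2019-06-21")) # ~ +23.44
#' solar_declination(as.Date("2019-12-21")) # ~ -23.44
#' @export
solar_declination <- function(date, hour_utc = 12) {
  doy <- if (inherits(date, "Date")) {
    as.numeric(format(date, "%j"))
  } else if (is.numeric(date)) {
    ((date - 1) %% 365) + 1
  } else {
    abort("`date` must be a Date or numeric day-of-year.")
  }
  g <- 2 * pi / 365 * (doy - 1 + (hour_utc - 12) / 24)
  decl_rad <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  # the truncated series can overshoot the obliquity by a few millidegrees
  pmin(pmax(decl_rad * 180 / pi, -23.45), 23.45)
}

# Maximum solar altitude (degrees, at local solar noon) for a civil day at a
# site. Declination is evaluated at local solar noon, i.e. 12 - lon/15 UTC.
max_solar_altitude <- function(date, lat_deg, lon_deg) {
  decl <- solar_declination(date, hour_utc = 12 - lon_deg / 15)
  90 - abs(lat_deg - decl)
}

june_solstice <- function(year) {
  # day of maximal declination; June 20-22 depending on year
  cand <- as.Date(sprintf("%d-06-%02d", year, 18:24))
  cand[which.max(solar_declination(cand))]
}

#' First sunrise after midwinter
#'
#' At high southern latitudes the sun stays below the horizon around the
#' June solstice (polar night). This returns the first civil day on or after
#' the June solstice on which the sun crosses the local horizon, the
#' astronomical anchor used to place arrival dates when count data are too
#' sparse to estimate them.
#'
#' A day counts as having a sunrise when the maximum solar altitude (at
#' local solar noon) exceeds `horizon` degrees. The default `horizon = 0`
#' (geometric rise of the solar centre) reproduces the expected midwinter
#' sunrise dates at both reference colonies to within a day; sites without a
#' polar night (e.g. north of the polar circle) return the solstice date
#' itself.
#'
#' @param site A [colony_site()].
#' @param year Calendar year of the June solstice.
#' @param horizon Altitude threshold in degrees defining a sunrise.
#' @return A `Date`.
#' @examples
#' pg <- colony_site("Pointe Geologie", -(66 + 40 / 60), 140 + 1 / 60)
#' first_sunrise_after_midwinter(pg, 2019) # late June
#' @export
first_sunrise_after_midwinter <- function(site, year, horizon = 0) {
  stopifnot(inherits(site, "colony_site"))
  if (!is.numeric(year) || length(year) != 1 || year != round(year)) {
    abort("`year` must be a single integer calendar year.")
  }
  start <- june_solstice(year)
  days <- start + 0:120
  alt <- max_solar_altitude(days, site$lat_deg, site$lon_deg)
  idx <- which(alt > horizon)
  if (length(idx) == 0) {
    abort(sprintf("no sunrise within 120 days of the solstice at latitude %.2f.",
                  site$lat_deg))
  }
  days[idx[1]]
}
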