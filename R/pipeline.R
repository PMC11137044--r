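# End-to-end recipe for a remotely sensed colony: (1) measured areas at
# image times, (2) weather at those times -> density via the windchill
# model, (3) N = rho * A with same-day averaging, (4) satellite-mode
# phenological fit -> breeding pairs, fledging success, conversion factor.

#' Convert colony areas to individual counts
#'
#' Matches each area measurement to the nearest weather record within a
#' tolerance, predicts colony density with the windchill model, multiplies
#' density by area, and averages within civil days.
#'
#' @param areas Data frame with `timestamp` (POSIXct UTC) and `area_m2`.
#' @param weather Data frame with `timestamp` and the weather columns.
#' @param wc_params A [windchill_params()] object.
#' @param season_year Calendar year of the season start; adds a `day`
#'   column on the season's day-of-year axis.
#' @param match_window_mins Maximum timestamp mismatch; unmatched areas are
#'   skipped with a warning listing them.
#' @return A tibble: `date`, `day`, `count`, `n_obs` (images per day).
#' @export
areas_to_counts <- function(areas, weather, wc_params, season_year,
                            match_window_mins = 30) {
  areas <- tibble::as_tibble(areas)
  weather <- tibble::as_tibble(weather)
  if (nrow(weather) == 0) abort("the weather stream is empty; cannot predict density.")
  if (nrow(areas) == 0) abort("the area stream is empty.")
  check_weather_frame(weather)
  wt <- as.numeric(weather$timestamp)
  ord <- order(wt)
  weather <- weather[ord, ]; wt <- wt[ord]
  at <- as.numeric(areas$timestamp)
  idx <- pmax(1, pmin(length(wt), findInterval(at, wt)))
  idx_up <- pmin(length(wt), idx + 1)
  nearest <- ifelse(abs(wt[idx_up] - at) < abs(wt[idx] - at), idx_up, idx)
  gap_min <- abs(wt[nearest] - at) / 60
  ok <- gap_min <= match_window_mins
  if (any(!ok)) {
    warn(paste0("no weather within ", match_window_mins, " min for ",
                sum(!ok), " image(s): ",
                paste(format(areas$timestamp[!ok], tz = "UTC"), collapse = ", "),
                "; skipped."))
  }
  if (!any(ok)) abort("no area measurement could be matched to weather.")
  matched <- dplyr::bind_cols(
    areas[ok, c("timestamp", "area_m2")],
    predict_density(weather[nearest[ok], c("temp_c", "wind_ms", "rad_wm2",
                                           "rh_pct")], wc_params)
  )
  matched$count <- counts_from_area(matched$area_m2, matched$density)
  out <- daily_average_counts(matched, col = "count")
  out$day <- date_to_doy(out$date, season_year)
  out[, c("date", "day", "count", "n_obs")]
}

#' Breeding-pair conversion factor
#'
#' The time-honoured satellite census shortcut multiplies colony area by a
#' constant breeding pairs per m2. Given a model-estimated `BP` this
#' computes that factor for the season, `CF = BP / mean(A)` over a
#' reference window.
#'
#' @param BP Estimated breeding pairs (> 0).
#' @param areas Numeric areas (m2) or a data frame with `area_m2` (and
#'   optionally `day` for windowing).
#' @param window Optional day-of-year range `c(lo, hi)` restricting which
#'   areas enter the mean.
#' @return Breeding pairs per m2.
#' @export
conversion_factor <- function(BP, areas, window = NULL) {
  if (!is.numeric(BP) || BP <= 0) abort("`BP` must be > 0.")
  if (is.data.frame(areas)) {
    if (!is.null(window)) {
      if (!"day" %in% names(areas)) abort("windowing needs a `day` column.")
      areas <- areas[areas$day >= window[1] & areas$day <= window[2], ]
    }
    areas <- areas$area_m2
  }
  if (length(areas) == 0) abort("no areas in the reference window.")
  if (mean(areas) <= 0) abort("mean area must be > 0.")
  BP / mean(areas)
}

#' Run the area-to-abundance pipeline
#'
#' Executes the full recipe on one season of imagery-derived areas plus
#' weather: windchill density prediction, daily-averaged counts, the
#' constrained satellite-mode fit, and the conversion factor. All
#' intermediates can be written to `out_dir` together with a run manifest;
#' the run is deterministic given `seed`.
#'
#' @param areas,weather Data frames as in [areas_to_counts()].
#' @param site A [colony_site()].
#' @param season_year Season start year.
#' @param wc_params Windchill parameters ([windchill_params()] or a
#'   [fit_windchill()] result, in which case posterior means are used).
#' @param defaults Fixed phenology defaults for the satellite fit.
#' @param config MCMC configuration for [fit_satellite()].
#' @param seed Integer seed (mandatory).
#' @param cf_window Optional day-of-year window for [conversion_factor()];
#'   default uses all supplied areas.
#' @param match_window_mins Weather matching tolerance in minutes.
#' @param out_dir Optional output directory; writes `counts.csv`,
#'   `posterior.csv`, `summary.json`, `report.md`, `manifest.json`.
#' @return A list of class `pipeline_result`: `counts`, `fit`, `BP`,
#'   `BP_sd`, `fledged`, `fledged_sd`, `conversion_factor`, `occupancy`,
#'   `diagnostics`.
#' @export
run_pipeline <- function(areas, weather, site, season_year,
                         wc_params = windchill_preset(),
                         defaults = phenology_preset("pointe-geologie"),
                         config = mcmc_defaults(n_walkers = 16, n_burn = 300,
                                                n_keep = 825),
                         seed, cf_window = NULL, match_window_mins = 30,
                         out_dir = NULL) {
  if (missing(seed)) abort("`seed` is mandatory for reproducibility.")
  if (inherits(wc_params, "windchill_fit")) {
    wc_params <- windchill_point_params(wc_params)
  }
  inform("pipeline stage 1/3: matching areas to weather and predicting counts")
  counts <- tryCatch(
    areas_to_counts(areas, weather, wc_params, season_year,
                    match_window_mins = match_window_mins),
    error = function(e) abort(paste0("stage areas_to_counts: ", conditionMessage(e))))
  inform(sprintf("pipeline stage 2/3: satellite-mode fit to %d daily counts (seed %d)",
                 nrow(counts), as.integer(seed)))
  fit <- tryCatch(
    fit_satellite(counts[, c("day", "count")], site, season_year,
                  defaults = defaults, config = config, seed = seed),
    error = function(e) abort(paste0("stage fit_satellite: ", conditionMessage(e))))
  inform("pipeline stage 3/3: deriving summaries")
  der <- derived_samples(fit)
  areas_cf <- tibble::as_tibble(areas)
  areas_cf$day <- date_to_doy(as.Date(areas_cf$timestamp, tz = "UTC"), season_year)
  cf <- conversion_factor(mean(fit$samples$BP), areas_cf, window = cf_window)
  occ <- occupancy(fit_point_params(fit))
  res <- structure(list(
    counts = counts, fit = fit,
    BP = mean(fit$samples$BP), BP_sd = sd(fit$samples$BP),
    fledged = mean(der$fledged), fledged_sd = sd(der$fledged),
    conversion_factor = cf, occupancy = occ,
    diagnostics = glance(fit), season_year = season_year,
    site = site, seed = as.integer(seed)
  ), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %s, season %d>\n", x$site$name, x$season_year))
  cat(sprintf("  breeding pairs: %.0f +/- %.0f\n", x$BP, x$BP_sd))
  cat(sprintf("  fledged chicks: %.0f +/- %.0f\n", x$fledged, x$fledged_sd))
  cat(sprintf("  conversion factor: %.3f breeding pairs / m2\n",
              x$conversion_factor))
  invisible(x)
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$counts, file.path(out_dir, "counts.csv"))
  readr::write_csv(res$fit$samples, file.path(out_dir, "posterior.csv"))
  summ <- list(
    site = res$site$name, season_year = res$season_year, seed = res$seed,
    BP = res$BP, BP_sd = res$BP_sd, fledged = res$fledged,
    fledged_sd = res$fledged_sd, conversion_factor = res$conversion_factor,
    diagnostics = as.list(res$diagnostics)
  )
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c(
    sprintf("# Pipeline report: %s, season %d", res$site$name, res$season_year),
    "",
    sprintf("- Breeding pairs: %.0f +/- %.0f", res$BP, res$BP_sd),
    sprintf("- Fledged chicks: %.0f +/- %.0f", res$fledged, res$fledged_sd),
    sprintf("- Conversion factor: %.3f breeding pairs / m2", res$conversion_factor),
    sprintf("- Daily counts fitted: %d", nrow(res$counts)),
    sprintf("- MCMC acceptance: %.2f; min ESS: %.0f",
            res$diagnostics$acceptance, res$diagnostics$ess_min),
    sprintf("- Seed: %d", res$seed)
  )
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(res)
}
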