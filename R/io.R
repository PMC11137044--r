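# CSV dialects shared by all tools. Dates are ISO-8601; timestamps UTC.
# Season indexing: day-of-season 0 = March 1 (day-of-year 60 on the
# non-leap reference calendar used throughout).

stop_rows <- function(what, rows, path) {
  abort(sprintf("%s in %s at row(s): %s", what, path,
                paste(head(rows, 10), collapse = ", ")))
}

#' Read a count series
#'
#' Expects columns `date` (ISO-8601), `n_adults`, and optionally
#' `n_chicks` (empty entries allowed). Rows are date-sorted and validated;
#' offending rows are named in errors.
#'
#' @param path CSV path.
#' @return A tibble `date`, `n_adults`, `n_chicks` (NA when not recorded),
#'   with attribute `kind` = `"adults_only"` or `"total"`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  need <- c("date", "n_adults")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  dates <- if (inherits(df$date, "Date")) df$date else
    as.Date(as.character(df$date), format = "%Y-%m-%d")
  if (any(is.na(dates))) stop_rows("unparseable date", which(is.na(dates)), path)
  df$date <- dates
  if (!"n_chicks" %in% names(df)) df$n_chicks <- NA_real_
  for (col in c("n_adults", "n_chicks")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) stop_rows(sprintf("negative %s", col), bad, path)
  }
  out <- dplyr::arrange(tibble::as_tibble(df[c("date", "n_adults", "n_chicks")]),
                        .data$date)
  attr(out, "kind") <- if (all(is.na(out$n_chicks))) "adults_only" else "total"
  out
}

#' @rdname read_counts
#' @param counts Tibble with `date`, `n_adults`, optional `n_chicks`.
#' @param path Output CSV path.
#' @export
write_counts <- function(counts, path) {
  counts <- tibble::as_tibble(counts)
  if (!"n_chicks" %in% names(counts)) counts$n_chicks <- NA_real_
  readr::write_csv(counts[, c("date", "n_adults", "n_chicks")], path)
  invisible(path)
}

#' Read a weather series
#'
#' Expects `timestamp` (ISO-8601, UTC), `temp_c`, `wind_ms`, `rad_wm2`,
#' `rh_pct`. Physical bounds are enforced (wind and radiation >= 0,
#' humidity 0..100); duplicate timestamps are kept (they are averaged later
#' where daily values are needed).
#'
#' @param path CSV path.
#' @return A tibble sorted by timestamp.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("timestamp", "temp_c", "wind_ms", "rad_wm2", "rh_pct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC")
  if (any(is.na(ts))) stop_rows("unparseable timestamp", which(is.na(ts)), path)
  df$timestamp <- ts
  bad <- which(df$wind_ms < 0 | df$rad_wm2 < 0 | df$rh_pct < 0 | df$rh_pct > 100)
  if (length(bad) > 0) stop_rows("out-of-range weather value", bad, path)
  dplyr::arrange(tibble::as_tibble(df[need]), .data$timestamp)
}

#' @rdname read_weather
#' @param weather Tibble with the weather columns.
#' @export
write_weather <- function(weather, path) {
  need <- c("timestamp", "temp_c", "wind_ms", "rad_wm2", "rh_pct")
  readr::write_csv(tibble::as_tibble(weather)[, need], path)
  invisible(path)
}

#' Read colony-area measurements
#'
#' Expects `timestamp` (ISO-8601 UTC) and `area_m2` (> 0).
#'
#' @param path CSV path.
#' @return A tibble sorted by timestamp.
#' @export
read_areas <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("timestamp", "area_m2"), names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC")
  if (any(is.na(ts))) stop_rows("unparseable timestamp", which(is.na(ts)), path)
  df$timestamp <- ts
  bad <- which(!is.finite(df$area_m2) | df$area_m2 <= 0)
  if (length(bad) > 0) stop_rows("non-positive area", bad, path)
  dplyr::arrange(tibble::as_tibble(df[c("timestamp", "area_m2")]),
                 .data$timestamp)
}

#' @rdname read_areas
#' @param areas Tibble with `timestamp`, `area_m2`.
#' @export
write_areas <- function(areas, path) {
  readr::write_csv(tibble::as_tibble(areas)[, c("timestamp", "area_m2")], path)
  invisible(path)
}

#' Read a colony-site YAML file
#'
#' Keys: `name`, `lat_deg`, `lon_deg`.
#'
#' @param path YAML path.
#' @return A [colony_site()].
#' @export
read_site_yaml <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  y <- yaml::read_yaml(path)
  miss <- setdiff(c("name", "lat_deg", "lon_deg"), names(y))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing key(s): %s", path, paste(miss, collapse = ", ")))
  }
  colony_site(y$name, y$lat_deg, y$lon_deg)
}

#' Write a reproducibility manifest for a run
#'
#' Records the command, seed, package version, timestamp, and MD5 checksums
#' of the input files — enough to reproduce the run exactly.
#'
#' @param command Name of the command/stage.
#' @param seed Integer seed used.
#' @param inputs Named character vector of input file paths.
#' @param extra Optional named list merged into the manifest.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, seed, inputs = character(0),
                           extra = list(), path) {
  checksums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- c(list(
    command = command,
    seed = as.integer(seed),
    package = "colonyphen",
    version = as.character(utils::packageVersion("colonyphen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    input_md5 = checksums
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
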