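# Parameter order used throughout the inference machinery.
phen_par_names <- function() {
  c("t0", "dt0", "m", "b", "db", "BP", "NB", "Hr", "F",
    "c_max", "c_min", "s_max", "s_min", "s_fem")
}

# Fixed box limits (lower, upper) for each parameter; relational limits
# (c_min <= c_max, c_max <= s_min <= s_max, s_fem in [c_max, s_max],
# F <= Hr, db >= dt0) are checked separately.
phen_par_box <- function() {
  rbind(
    t0    = c(50, 150),   # day-of-year; 50 ~ Feb 20, 150 ~ May 30
    dt0   = c(4, 14),
    m     = c(28, 42),
    b     = c(50, 100),
    db    = c(0, 14),
    BP    = c(2000, 15000),
    NB    = c(0, 1),
    Hr    = c(0, 1),
    F     = c(0, 1),
    c_max = c(1, 5),
    c_min = c(1, 5),
    s_max = c(1, 21),
    s_min = c(1, 21),
    s_fem = c(1, 21)
  )
}

#' Phenological model parameters
#'
#' The 14 parameters describing one colony-season: arrival timing, courtship
#' and incubation durations, cohort sizes and success ratios, and the
#' foraging-trip duration ramp. Together they determine the full event
#' schedule and daily occupancy of the colony.
#'
#' @param t0 Peak arrival date, day-of-year (50-150).
#' @param dt0 Standard deviation of individual arrival dates, days (4-14).
#'   Also the sd of the courtship departure, since courtship length is
#'   assumed equal across breeders.
#' @param m Courtship duration: days between arrival and the females' first
#'   departure (28-42).
#' @param b Female absence duration (male incubation), days (50-100).
#' @param db Standard deviation of the female return and all later events,
#'   days (0-14, and at least `dt0`).
#' @param BP Number of breeding pairs (2000-15000).
#' @param NB Ratio of non-breeding birds to breeding pairs (0-1).
#' @param Hr Hatching success: fraction of pairs still returning after
#'   incubation (0-1).
#' @param F Fledging success: fraction of pairs returning until the end of
#'   chick rearing (0-1, at most `Hr`).
#' @param c_max,c_min Maximum/minimum time at the colony per foraging trip,
#'   days; the per-trip colony stay ramps linearly from `c_max` (first trip)
#'   to `c_min` (last).
#' @param s_max,s_min Maximum/minimum time at sea per trip, days; ramps
#'   linearly from `s_max` to `s_min` across the crèche trips.
#' @param s_fem Duration of the females' first post-hatch foraging trip,
#'   days; shorter than or equal to the males' first trip (`s_max`).
#' @return An object of class `phenology_params` (named list).
#' @examples
#' phenology_preset("pointe-geologie")
#' @export
phenology_params <- function(t0, dt0, m, b, db, BP, NB, Hr, F,
                             c_max, c_min, s_max, s_min, s_fem) {
  p <- list(t0 = t0, dt0 = dt0, m = m, b = b, db = db, BP = BP, NB = NB,
            Hr = Hr, F = F, c_max = c_max, c_min = c_min, s_max = s_max,
            s_min = s_min, s_fem = s_fem)
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1 || !is.finite(v),
                logical(1))
  if (any(bad)) {
    abort(paste0("non-finite or non-scalar parameter(s): ",
                 paste(names(p)[bad], collapse = ", ")))
  }
  problems <- validate_phenology_params(p)
  if (length(problems) > 0) {
    abort(paste0("invalid phenology parameters:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  structure(p, class = "phenology_params")
}

#' Validate phenological parameters
#'
#' Checks the box limits and the relational constraints
#' (`c_min <= c_max <= s_min <= s_max`, `c_max <= s_fem <= s_max`,
#' `F <= Hr`, `db >= dt0`).
#'
#' @param p A named list or `phenology_params` object.
#' @return A character vector of violations (empty when valid).
#' @export
validate_phenology_params <- function(p) {
  box <- phen_par_box()
  out <- character(0)
  for (nm in rownames(box)) {
    v <- p[[nm]]
    if (is.null(v)) {
      out <- c(out, sprintf("missing parameter `%s`", nm))
    } else if (v < box[nm, 1] || v > box[nm, 2]) {
      out <- c(out, sprintf("`%s` = %.4g outside [%.4g, %.4g]",
                            nm, v, box[nm, 1], box[nm, 2]))
    }
  }
  if (length(out) > 0) return(out)
  if (p$c_min > p$c_max) out <- c(out, "`c_min` must be <= `c_max`")
  if (p$s_min < p$c_max) out <- c(out, "`s_min` must be >= `c_max`")
  if (p$s_min > p$s_max) out <- c(out, "`s_min` must be <= `s_max`")
  if (p$s_max < p$c_max) out <- c(out, "`s_max` must be >= `c_max`")
  if (p$s_fem < p$c_max || p$s_fem > p$s_max) {
    out <- c(out, "`s_fem` must be within [`c_max`, `s_max`]")
  }
  if (p$F > p$Hr) out <- c(out, "`F` (fledging) must be <= `Hr` (hatching)")
  if (p$db < p$dt0) out <- c(out, "`db` must be >= `dt0`")
  out
}

#' @export
print.phenology_params <- function(x, ...) {
  cat("<phenology_params>\n")
  v <- unlist(x[phen_par_names()])
  cat(paste0("  ", format(names(v), width = 6), " = ", signif(v, 5),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Preset colony-season parameter sets
#'
#' Two synthetic reference parameter sets probing realistic regimes: a
#' "pointe-geologie"-like season (about 3900 pairs, early-April arrival
#' peak) and an "atka-bay"-like season (about 8600 pairs, late-April
#' arrival). These are the generator truths and the satellite-mode fixed
#' defaults; they are constructed values, not field-fitted estimates.
#'
#' @param site `"pointe-geologie"` or `"atka-bay"`.
#' @return A [phenology_params()] object.
#' @export
phenology_preset <- function(site = c("pointe-geologie", "atka-bay")) {
  site <- match.arg(site)
  switch(site,
    "pointe-geologie" = phenology_params(
      t0 = 97, dt0 = 6, m = 35, b = 64, db = 8, BP = 3900, NB = 0.15,
      Hr = 0.85, F = 0.70, c_max = 3, c_min = 1.5, s_max = 18, s_min = 8,
      s_fem = 10),
    "atka-bay" = phenology_params(
      t0 = 117, dt0 = 7, m = 35, b = 64, db = 9, BP = 8600, NB = 0.15,
      Hr = 0.85, F = 0.65, c_max = 3, c_min = 1.5, s_max = 18, s_min = 8,
      s_fem = 10)
  )
}

#' Draw random valid parameter sets
#'
#' Uniform rejection sampling inside the parameter box and relational
#' constraints, used by property tests and prior-predictive checks.
#'
#' @param n Number of parameter sets.
#' @param within_season Require the implied fledging date to fall before the
#'   season end (Feb 28)?
#' @return A list of `phenology_params` objects.
#' @export
random_phenology_params <- function(n, within_season = TRUE) {
  box <- phen_par_box()
  draw_one <- function() {
    repeat {
      v <- setNames(runif(nrow(box), box[, 1], box[, 2]), rownames(box))
      p <- as.list(v)
      if (length(validate_phenology_params(p)) > 0) next
      p <- structure(p, class = "phenology_params")
      if (within_season) {
        core <- schedule_core(p)
        if (max(core$mean) > season_end_doy()) next
      }
      return(p)
    }
  }
  lapply(seq_len(n), function(i) draw_one())
}

# params <-> numeric vector in canonical order
par_to_vec <- function(p) unlist(p[phen_par_names()], use.names = TRUE)
vec_to_par <- function(v) {
  structure(as.list(setNames(as.numeric(v), phen_par_names())),
            class = "phenology_params")
}
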