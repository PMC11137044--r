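# Forward phenological model: the 14 parameters define a fixed, ordered set
# of Gaussian-shaped arrival/departure events per cohort (female breeders,
# male breeders, non-breeders, chicks); expected daily occupancy is the
# signed sum of the event CDFs.

#' Per-trip foraging durations
#'
#' The fixed trip structure of the model: 2 foraging trips per sex during
#' the guarding phase (at sea `s_max`, at colony `c_max`; the females' first
#' trip is the shorter `s_fem`) and 7 trips per sex during the creching
#' phase, whose at-sea and at-colony durations shrink linearly from
#' (`s_max`, `c_max`) on trip 1 to (`s_min`, `c_min`) on trip 7.
#'
#' @param p A [phenology_params()] object.
#' @return A tibble with columns `sex`, `phase`, `trip`, `at_sea`,
#'   `at_colony` (days).
#' @examples
#' trip_durations(phenology_preset("pointe-geologie"))
#' @export
trip_durations <- function(p) {
  stopifnot(inherits(p, "phenology_params"))
  k <- 1:7
  s_k <- p$s_max - (k - 1) * (p$s_max - p$s_min) / 6
  c_k <- p$c_max - (k - 1) * (p$c_max - p$c_min) / 6
  dplyr::bind_rows(
    tibble::tibble(sex = "female", phase = "guarding", trip = 1:2,
                   at_sea = c(p$s_fem, p$s_max), at_colony = p$c_max),
    tibble::tibble(sex = "male", phase = "guarding", trip = 1:2,
                   at_sea = p$s_max, at_colony = p$c_max),
    tibble::tibble(sex = "female", phase = "creching", trip = k,
                   at_sea = s_k, at_colony = c_k),
    tibble::tibble(sex = "male", phase = "creching", trip = k,
                   at_sea = s_k, at_colony = c_k)
  )
}

#' Total creching-phase time at sea and at the colony
#'
#' Sums the 7 creching-trip durations and averages females and males. These
#' totals are the foraging-effort summaries whose relationship with breeding
#' success downstream analyses examine.
#'
#' @param p A [phenology_params()] object.
#' @return A tibble with one row: `at_sea`, `at_colony` (days).
#' @export
total_time_at_sea_colony <- function(p) {
  td <- trip_durations(p) |> dplyr::filter(.data$phase == "creching")
  td |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(at_sea = sum(.data$at_sea),
                     at_colony = sum(.data$at_colony), .groups = "drop") |>
    dplyr::summarise(at_sea = mean(.data$at_sea),
                     at_colony = mean(.data$at_colony))
}

# Internal numeric schedule: event means/sds/magnitudes per cohort, on the
# continuous day-of-year axis. `overlap` is the parental switching overlap
# at the female return (days).
schedule_core <- function(p, overlap = 1) {
  t_H <- p$t0 + p$m + p$b
  k <- 1:7
  s_k <- p$s_max - (k - 1) * (p$s_max - p$s_min) / 6
  c_k <- p$c_max - (k - 1) * (p$c_max - p$c_min) / 6
  surv <- p$Hr - k * (p$Hr - p$F) / 7          # pair-survival after trip k
  BP <- p$BP

  mean_v <- numeric(0); sd_v <- numeric(0); mag_v <- numeric(0)
  coh_v <- integer(0); lab_v <- character(0)
  push <- function(mean, sd, mag, coh, lab) {
    mean_v <<- c(mean_v, mean); sd_v <<- c(sd_v, sd); mag_v <<- c(mag_v, mag)
    coh_v <<- c(coh_v, coh); lab_v <<- c(lab_v, lab)
  }
  FEM <- 1L; MAL <- 2L; NBR <- 3L; CHK <- 4L

  # arrival and courtship
  push(p$t0, p$dt0, BP, FEM, "arrival")
  push(p$t0, p$dt0, BP, MAL, "arrival")
  push(p$t0, p$dt0, p$NB * BP, NBR, "arrival")
  push(p$t0 + p$m, p$dt0, -BP, FEM, "courtship_departure")
  push(p$t0 + p$m, p$dt0, -p$NB * BP, NBR, "courtship_departure")

  # female return at hatching; only successful pairs' females keep feeding
  push(t_H, p$db, p$Hr * BP, FEM, "female_return")
  # all males leave shortly after the females return (1-day overlap)
  push(t_H + overlap, p$db, -BP, MAL, "male_departure")

  # guarding phase: 2 trips per sex (female's first at sea = s_fem)
  tf <- t_H                                    # female present since t_H
  f_sea <- c(p$s_fem, p$s_max)
  for (g in 1:2) {
    push(tf + p$c_max, p$db, -p$Hr * BP, FEM, sprintf("guard_departure_%d", g))
    tf <- tf + p$c_max + f_sea[g]
    push(tf, p$db, p$Hr * BP, FEM, sprintf("guard_return_%d", g))
  }
  emanc_f <- tf + p$c_max
  push(emanc_f, p$db, -p$Hr * BP, FEM, "emancipation_departure")

  tm <- t_H + overlap                          # male leaves, then 2 trips
  for (g in 1:2) {
    tm <- tm + p$s_max
    push(tm, p$db, p$Hr * BP, MAL, sprintf("guard_return_%d", g))
    if (g < 2) {
      push(tm + p$c_max, p$db, -p$Hr * BP, MAL, sprintf("guard_departure_%d", g + 1))
      tm <- tm + p$c_max
    }
  }
  emanc_m <- tm + p$c_max
  push(emanc_m, p$db, -p$Hr * BP, MAL, "emancipation_departure")

  # chicks become countable at thermal emancipation
  emanc <- (emanc_f + emanc_m) / 2
  push(emanc, p$db, p$Hr * BP, CHK, "emancipation_entry")

  # creching phase: 7 feeding/foraging trips per sex with linear attrition
  ret_f <- numeric(7); ret_m <- numeric(7)
  tf <- emanc_f; tm <- emanc_m
  for (i in k) {
    tf <- tf + s_k[i]; ret_f[i] <- tf
    push(tf, p$db, surv[i] * BP, FEM, sprintf("creche_return_%d", i))
    tm <- tm + s_k[i]; ret_m[i] <- tm
    push(tm, p$db, surv[i] * BP, MAL, sprintf("creche_return_%d", i))
    if (i < 7) {
      push(tf + c_k[i], p$db, -surv[i] * BP, FEM, sprintf("creche_departure_%d", i))
      push(tm + c_k[i], p$db, -surv[i] * BP, MAL, sprintf("creche_departure_%d", i))
      tf <- tf + c_k[i]; tm <- tm + c_k[i]
    }
  }
  # chick losses: pairs failing at trip i abandon around the would-be return
  att <- (p$Hr - p$F) / 7
  for (i in k) {
    push((ret_f[i] + ret_m[i]) / 2, p$db, -att * BP, CHK,
         sprintf("creche_loss_%d", i))
  }
  # fledging empties surviving chicks and both parents
  fledge_f <- ret_f[7] + c_k[7]
  fledge_m <- ret_m[7] + c_k[7]
  push(fledge_f, p$db, -p$F * BP, FEM, "fledging_departure")
  push(fledge_m, p$db, -p$F * BP, MAL, "fledging_departure")
  push((fledge_f + fledge_m) / 2, p$db, -p$F * BP, CHK, "fledging_departure")

  list(mean = mean_v, sd = sd_v, mag = mag_v, cohort = coh_v, label = lab_v,
       t_H = t_H, emanc = emanc, fledge = (fledge_f + fledge_m) / 2,
       ret_f = ret_f, ret_m = ret_m)
}

cohort_names <- function() c("female", "male", "non_breeder", "chick")

#' Build the Gaussian event schedule
#'
#' Expands a parameter set into the model's fixed, ordered list of signed
#' Gaussian phenological events per cohort: arrival, courtship departure,
#' female return / male departure at hatching, two guarding trips per sex,
#' chick emancipation, seven creching trips per sex with linear pair
#' attrition from `Hr` to `F`, and fledging. Positive magnitudes are
#' arrivals, negative are departures.
#'
#' @param p A [phenology_params()] object.
#' @param overlap Parental switching overlap at the female return, days.
#' @return A tibble of class `event_schedule` with columns `event`,
#'   `cohort`, `mean_day` (day-of-year; values beyond 365 fall in the next
#'   calendar year), `sd_day`, and `magnitude` (individuals, signed).
#' @examples
#' build_event_schedule(phenology_preset("pointe-geologie"))
#' @export
build_event_schedule <- function(p, overlap = 1) {
  stopifnot(inherits(p, "phenology_params"))
  core <- schedule_core(p, overlap = overlap)
  if (max(core$mean) > season_end_doy()) {
    abort(sprintf(
      "schedule extends to day %.1f, beyond the season end (Feb 28 = day %d).",
      max(core$mean), season_end_doy()))
  }
  out <- tibble::tibble(
    event = core$label,
    cohort = cohort_names()[core$cohort],
    mean_day = core$mean,
    sd_day = core$sd,
    magnitude = core$mag
  ) |>
    dplyr::arrange(.data$cohort, .data$mean_day)
  attr(out, "params") <- p
  attr(out, "overlap") <- overlap
  class(out) <- c("event_schedule", class(out))
  out
}

# Fast numeric occupancy: cohort counts at `days` from a schedule core.
# Returns a days x 4 matrix (female, male, non_breeder, chick).
occupancy_matrix <- function(core, days) {
  z <- outer(days, core$mean, "-") / rep(core$sd, each = length(days))
  P <- pnorm(z)
  out <- matrix(0, length(days), 4)
  for (coh in 1:4) {
    sel <- core$cohort == coh
    if (any(sel)) out[, coh] <- P[, sel, drop = FALSE] %*% core$mag[sel]
  }
  pmax(out, 0)   # clip floating-point undershoot
}

#' Expected daily occupancy
#'
#' Sums the signed cumulative Gaussians of all events to the expected number
#' of individuals of each cohort present per day.
#'
#' @param schedule An [build_event_schedule()] result or a
#'   [phenology_params()] object (in which case the schedule is built
#'   internally).
#' @param days Numeric day-of-year grid; defaults to the full season
#'   (March 1 to Feb 28, days 60..424).
#' @return A tibble of class `occupancy_curve`: `day`, `female`, `male`,
#'   `non_breeder`, `chick`, `adults` (sum of the first three) and `total`.
#' @examples
#' occ <- occupancy(phenology_preset("pointe-geologie"))
#' @export
occupancy <- function(schedule, days = seq(season_start_doy(), season_end_doy())) {
  if (inherits(schedule, "phenology_params")) {
    core <- schedule_core(schedule)
  } else if (inherits(schedule, "event_schedule")) {
    core <- list(
      mean = schedule$mean_day, sd = schedule$sd_day, mag = schedule$magnitude,
      cohort = match(schedule$cohort, cohort_names())
    )
  } else {
    abort("`schedule` must be an event_schedule or phenology_params object.")
  }
  m <- occupancy_matrix(core, days)
  out <- tibble::tibble(
    day = days, female = m[, 1], male = m[, 2], non_breeder = m[, 3],
    chick = m[, 4]
  ) |>
    dplyr::mutate(adults = .data$female + .data$male + .data$non_breeder,
                  total = .data$adults + .data$chick)
  class(out) <- c("occupancy_curve", class(out))
  out
}

#' Breeding outcome implied by a parameter set
#'
#' Exact bookkeeping: every breeding pair ends the season as a fledged
#' chick, a dead chick, or a lost egg; the three counts always sum to `BP`.
#'
#' @param p A [phenology_params()] object.
#' @return A one-row tibble: `fledged`, `dead_chicks`, `lost_eggs`.
#' @examples
#' breeding_outcome(phenology_preset("pointe-geologie"))
#' @export
breeding_outcome <- function(p) {
  stopifnot(inherits(p, "phenology_params"))
  if (p$F > p$Hr) abort("`F` must be <= `Hr`.")
  tibble::tibble(
    fledged = p$F * p$BP,
    dead_chicks = (p$Hr - p$F) * p$BP,
    lost_eggs = (1 - p$Hr) * p$BP
  )
}

#' Central dates of the named phenological events
#'
#' Mean (central) event dates derived from the schedule: arrival, female
#' departure, female return, hatching (`t0 + m + b`, coinciding with the
#' female return), chick emancipation, and fledging. Field records usually
#' log the *first* occurrence of a behaviour, which precedes these central
#' dates systematically; no correction is applied.
#'
#' @param p A [phenology_params()] object.
#' @param season_year Optional calendar year of the season start (March 1);
#'   when given, a `date` column is added.
#' @return A tibble: `event`, `day` (day-of-year), and optionally `date`.
#' @export
event_dates <- function(p, season_year = NULL) {
  stopifnot(inherits(p, "phenology_params"))
  core <- schedule_core(p)
  out <- tibble::tibble(
    event = c("arrival", "female_departure", "female_return", "hatching",
              "emancipation", "fledging"),
    day = c(p$t0, p$t0 + p$m, core$t_H, core$t_H, core$emanc, core$fledge)
  )
  if (!is.null(season_year)) out$date <- doy_to_date(out$day, season_year)
  out
}

# day-of-year (possibly > 365, non-leap reference) -> Date for a season
# starting March 1 of `season_year`.
doy_to_date <- function(day, season_year) {
  as.Date(sprintf("%d-01-01", season_year)) + (round(day) - 1)
}

# Date -> continuous day-of-year on the season axis of `season_year`
# (Jan/Feb dates of the following year map to 366..424).
date_to_doy <- function(date, season_year) {
  d <- as.numeric(format(date, "%j"))
  yr <- as.numeric(format(date, "%Y"))
  # normalise leap-year doy after Feb to the non-leap reference
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  d <- ifelse(leap & d > 60, d - 1, d)
  d + 365 * (yr - season_year)
}

#' Agent-based simulation oracle
#'
#' Simulates `n_pairs` breeding pairs (plus the proportional non-breeder
#' cohort) as individuals: each bird draws a Gaussian timing offset for its
#' arrival/courtship block and another for everything after the female
#' return (so one late bird is late throughout, and courtship is equally
#' long for every breeder), each pair hatches with probability `Hr` and,
#' given hatching, fails at creching trip k with equal per-trip probability
#' so that overall fledging success is `F`. Every individual event time is
#' therefore marginally the schedule's Gaussian, making the expected daily
#' counts (scaled by `n_pairs / BP`) exactly the analytic [occupancy()]
#' curve while per-day counts are sums of independent 0/1 presences — an
#' independent Monte-Carlo check of the event bookkeeping with binomial
#' sampling error.
#'
#' @param p A [phenology_params()] object.
#' @param n_pairs Number of simulated pairs (>= 1).
#' @param seed Integer seed; the output is reproducible from `(p, n_pairs,
#'   seed)`.
#' @param days Day-of-year grid (defaults to the full season).
#' @param overlap Parental switching overlap, days.
#' @return A tibble like [occupancy()] (integer cohort counts), with
#'   attribute `n_pairs`.
#' @export
agent_oracle <- function(p, n_pairs, seed,
                         days = seq(season_start_doy(), season_end_doy()),
                         overlap = 1) {
  stopifnot(inherits(p, "phenology_params"), n_pairs >= 1)
  set.seed(as.integer(seed))
  core <- schedule_core(p, overlap = overlap)
  n <- as.integer(n_pairs)
  n_nb <- as.integer(round(p$NB * n))

  counts <- matrix(0, length(days), 4)
  add_event <- function(times, sign, coh) {
    if (length(times) == 0) return(invisible())
    counts[, coh] <<- counts[, coh] + sign * findInterval(days, sort(times))
    invisible()
  }
  ev_mean <- function(coh, lab) core$mean[core$cohort == coh & core$label == lab]
  FEM <- 1L; MAL <- 2L; NBR <- 3L; CHK <- 4L

  # per-bird timing offsets: one for the arrival/courtship block (sd dt0),
  # one for all post-return events (sd db)
  off_a_f <- rnorm(n, 0, p$dt0)
  off_a_m <- rnorm(n, 0, p$dt0)
  off_l_f <- rnorm(n, 0, p$db)
  off_l_m <- rnorm(n, 0, p$db)

  # pair fates: hatch with prob Hr; given hatching, fail at creche trip k
  # (k = 1..7) with equal probability so overall success is F
  hatched <- runif(n) < p$Hr
  n_h <- sum(hatched)
  fail_prob <- if (p$Hr > 0) (p$Hr - p$F) / p$Hr else 0
  u <- runif(n_h)
  death_trip <- rep(Inf, n_h)
  failing <- u < fail_prob
  if (any(failing)) {
    k_fail <- ceiling(u[failing] / (fail_prob / 7))
    death_trip[failing] <- pmin(k_fail, 7)
  }

  add_event(p$t0 + off_a_f, +1, FEM)
  add_event(p$t0 + off_a_m, +1, MAL)
  add_event(p$t0 + p$m + off_a_f, -1, FEM)
  if (n_nb > 0) {
    off_a_nb <- rnorm(n_nb, 0, p$dt0)
    add_event(p$t0 + off_a_nb, +1, NBR)
    add_event(p$t0 + p$m + off_a_nb, -1, NBR)
  }
  add_event(core$t_H + overlap + off_l_m, -1, MAL)

  if (n_h > 0) {
    hf <- off_l_f[hatched]; hm <- off_l_m[hatched]
    off_c <- rnorm(n_h, 0, p$db)
    guard <- list(
      list(FEM, "female_return", +1, quote(hf)),
      list(FEM, "guard_departure_1", -1, quote(hf)),
      list(FEM, "guard_return_1", +1, quote(hf)),
      list(FEM, "guard_departure_2", -1, quote(hf)),
      list(FEM, "guard_return_2", +1, quote(hf)),
      list(FEM, "emancipation_departure", -1, quote(hf)),
      list(MAL, "guard_return_1", +1, quote(hm)),
      list(MAL, "guard_departure_2", -1, quote(hm)),
      list(MAL, "guard_return_2", +1, quote(hm)),
      list(MAL, "emancipation_departure", -1, quote(hm))
    )
    for (ev in guard) {
      off <- eval(ev[[4]])
      add_event(ev_mean(ev[[1]], ev[[2]]) + off, ev[[3]], ev[[1]])
    }
    add_event(core$emanc + off_c, +1, CHK)
    for (i in 1:7) {
      alive <- death_trip > i          # pairs returning from trip i
      if (any(alive)) {
        add_event(ev_mean(FEM, sprintf("creche_return_%d", i)) + hf[alive], +1, FEM)
        add_event(ev_mean(MAL, sprintf("creche_return_%d", i)) + hm[alive], +1, MAL)
        if (i < 7) {
          add_event(ev_mean(FEM, sprintf("creche_departure_%d", i)) + hf[alive], -1, FEM)
          add_event(ev_mean(MAL, sprintf("creche_departure_%d", i)) + hm[alive], -1, MAL)
        }
      }
      dying <- death_trip == i         # chick abandoned around this return
      if (any(dying)) {
        add_event((core$ret_f[i] + core$ret_m[i]) / 2 + off_c[dying], -1, CHK)
      }
    }
    surv <- is.infinite(death_trip)
    if (any(surv)) {
      add_event(ev_mean(FEM, "fledging_departure") + hf[surv], -1, FEM)
      add_event(ev_mean(MAL, "fledging_departure") + hm[surv], -1, MAL)
      add_event(ev_mean(CHK, "fledging_departure") + off_c[surv], -1, CHK)
    }
  }
  out <- tibble::tibble(
    day = days, female = counts[, 1], male = counts[, 2],
    non_breeder = counts[, 3], chick = counts[, 4]
  ) |>
    dplyr::mutate(adults = .data$female + .data$male + .data$non_breeder,
                  total = .data$adults + .data$chick)
  attr(out, "n_pairs") <- n
  out
}
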