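# Bayesian estimation of the phenological parameters from count series.
#
# Observation model: counts are strictly positive and fluctuate
# multiplicatively, so errors are lognormal with a single season-level log
# standard deviation `sigma_log` estimated jointly (half-normal prior).
# Priors on the 14 phenology parameters are uniform on the physiological
# boxes with the model's ordering constraints.

sigma_log_prior_scale <- function() 0.5
count_floor <- function() 0.5  # animals; guards log(0) for empty colony days

#' Log-prior of the phenological parameters
#'
#' Uniform within the parameter box and ordering constraints; `-Inf`
#' outside. When `sigma_log` is supplied its half-normal prior is added.
#'
#' @param p A [phenology_params()] object, named list, or numeric vector in
#'   canonical order (see `tidy()` output of a fit for the order).
#' @param sigma_log Optional lognormal observation sd (> 0).
#' @return A log-density (finite constant inside the prior support).
#' @export
phenology_log_prior <- function(p, sigma_log = NULL) {
  if (is.numeric(p)) p <- as.list(setNames(p, phen_par_names()))
  lp <- if (length(validate_phenology_params(p)) > 0) -Inf else 0
  if (!is.null(sigma_log)) {
    lp <- lp + if (sigma_log <= 0) -Inf else
      -sigma_log^2 / (2 * sigma_log_prior_scale()^2)
  }
  lp
}

#' Lognormal count log-likelihood
#'
#' Independent lognormal errors around the model occupancy at the observed
#' days: `sum dnorm(log obs, log model, sigma_log)` with a small floor on
#' both sides guarding `log(0)` when the colony is empty.
#'
#' @param p A [phenology_params()] object (or named list/vector).
#' @param counts A data frame with `day` (day-of-year) and `count`.
#' @param sigma_log Lognormal sd (> 0).
#' @param kind `"adults"` to compare against the adult cohorts only (ground
#'   counts), `"total"` for adults + chicks (area-derived counts).
#' @return The log-likelihood.
#' @export
count_log_likelihood <- function(p, counts, sigma_log,
                                 kind = c("adults", "total")) {
  kind <- match.arg(kind)
  if (is.numeric(p)) p <- as.list(setNames(p, phen_par_names()))
  stopifnot(sigma_log > 0)
  core <- schedule_core(p)
  m <- occupancy_matrix(core, counts$day)
  model <- if (kind == "adults") rowSums(m[, 1:3, drop = FALSE]) else rowSums(m)
  fl <- count_floor()
  sum(dnorm(log(pmax(counts$count, fl)), log(pmax(model, fl)),
            sigma_log, log = TRUE))
}

#' Geometric (multiplicative) error
#'
#' Count data vary on a logarithmic scale, so errors are reported
#' multiplicatively: a 1.25-fold over- or underestimate is a 25% geometric
#' error, `(exp(|log(pred/obs)|) - 1) * 100`. Symmetric in its arguments and
#' zero iff `pred == obs`.
#'
#' @param pred,obs Positive predicted and observed values (vectorised).
#' @return Per-point geometric errors in percent.
#' @seealso [mean_geometric_error()] for the log-scale aggregate.
#' @examples
#' geometric_error(1.25, 1) # 25
#' @export
geometric_error <- function(pred, obs) {
  if (any(pred <= 0) || any(obs <= 0)) {
    abort("`pred` and `obs` must be strictly positive.")
  }
  (exp(abs(log(pred / obs))) - 1) * 100
}

#' Average geometric error of a set of predictions
#'
#' Aggregates per-point multiplicative errors on the log scale:
#' `(exp(mean |log(pred/obs)|) - 1) * 100`.
#'
#' @inheritParams geometric_error
#' @return A single percentage.
#' @export
mean_geometric_error <- function(pred, obs) {
  if (any(pred <= 0) || any(obs <= 0)) {
    abort("`pred` and `obs` must be strictly positive.")
  }
  (exp(mean(abs(log(pred / obs)))) - 1) * 100
}

# normalise a counts frame to (day, count); dates are mapped onto the
# season's continuous day-of-year axis.
normalise_counts <- function(counts, season_year = NULL) {
  counts <- tibble::as_tibble(counts)
  if (!"count" %in% names(counts)) abort("`counts` needs a `count` column.")
  if (!"day" %in% names(counts)) {
    if (!"date" %in% names(counts)) abort("`counts` needs a `day` or `date` column.")
    if (is.null(season_year)) {
      abort("`season_year` is required when counts carry dates.")
    }
    counts$day <- date_to_doy(as.Date(counts$date), season_year)
  }
  if (any(counts$count < 0)) abort("counts must be >= 0.")
  # several observations within one civil day are averaged before fitting
  counts |>
    dplyr::group_by(day = floor(.data$day)) |>
    dplyr::summarise(count = mean(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$day)
}

new_phen_fit <- function(samples, par_names, data, kind, mode, fixed,
                         acceptance, ess, config) {
  structure(list(samples = samples, par_names = par_names, data = data,
                 kind = kind, mode = mode, fixed = fixed,
                 acceptance = acceptance, ess = ess, config = config),
            class = "phen_fit")
}

#' MCMC configuration
#'
#' Ensemble-sampler settings. The defaults retain
#' `n_walkers * n_keep = 13200` posterior samples.
#'
#' @param n_walkers Number of walkers (even; at least twice the dimension).
#' @param n_burn Burn-in ensemble steps (discarded).
#' @param n_keep Retained ensemble steps.
#' @param thin Keep every `thin`-th step during the retained phase.
#' @return A list used by the `fit_*` functions.
#' @export
mcmc_defaults <- function(n_walkers = 44, n_burn = 800, n_keep = 300,
                          thin = 1) {
  list(n_walkers = n_walkers, n_burn = n_burn, n_keep = n_keep, thin = thin)
}

# data-driven starting guess for the full fit
full_fit_init <- function(counts, kind) {
  cmax <- max(counts$count)
  plateau <- cmax / 2.15                 # courtship plateau ~ (2 + NB) BP
  BP0 <- min(max(plateau, 2100), 14500)
  rise <- counts$day[which(counts$count >= 0.5 * cmax)[1]]
  t00 <- min(max(rise - 5, 55), 145)
  c(t0 = t00, dt0 = 7, m = 35, b = 70, db = 9, BP = BP0, NB = 0.15,
    Hr = 0.7, F = 0.5, c_max = 3, c_min = 2, s_max = 15, s_min = 8,
    s_fem = 10, sigma_log = 0.2)
}

#' Fit the full 14-parameter phenological model
#'
#' Posterior sampling of all phenology parameters plus the observation noise
#' `sigma_log` from a season's count series, using affine-invariant ensemble
#' MCMC. Ground-truth series are fitted as `kind = "adults"` (the chick
#' curve is then a genuine prediction); area-derived series use
#' `kind = "total"`. The default configuration retains 13,200 posterior
#' samples.
#'
#' @param counts Data frame with `day` (day-of-year) or `date` plus `count`.
#' @param kind Which curve the counts measure: `"adults"` or `"total"`.
#' @param season_year Calendar year of the season start (needed when
#'   `counts` has dates).
#' @param config MCMC configuration from [mcmc_defaults()].
#' @param seed Integer seed (mandatory; the fit is deterministic given it).
#' @param refine_start Run a Nelder-Mead ascent from the data-driven
#'   starting guess before seeding the walkers (recommended).
#' @return A `phen_fit` object; see [tidy.phen_fit()], [glance.phen_fit()],
#'   [predict.phen_fit()], [summary.phen_fit()].
#' @export
fit_phenology <- function(counts, kind = c("adults", "total"),
                          season_year = NULL, config = mcmc_defaults(),
                          seed, refine_start = TRUE) {
  kind <- match.arg(kind)
  if (missing(seed)) abort("`seed` is mandatory for reproducibility.")
  counts <- normalise_counts(counts, season_year)
  if (nrow(counts) < 10) {
    warn(sprintf("only %d count days; the full 14-parameter fit expects ~20+.",
                 nrow(counts)))
  }
  par_names <- c(phen_par_names(), "sigma_log")
  log_post <- function(v) {
    names(v) <- par_names
    lp <- phenology_log_prior(v[1:14], v["sigma_log"])
    if (!is.finite(lp)) return(-Inf)
    lp + count_log_likelihood(v[1:14], counts, v[["sigma_log"]], kind)
  }
  set.seed(as.integer(seed))
  start <- full_fit_init(counts, kind)
  if (!is.finite(log_post(start))) {
    start[c("Hr", "F")] <- c(0.6, 0.4)  # fall back to a looser guess
  }
  if (refine_start) {
    opt <- optim(start, function(v) -log_post(v), method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-8))
    opt <- optim(opt$par, function(v) -log_post(v), method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-8))
    if (is.finite(opt$value)) start <- opt$par
  }
  init <- init_ball(start, config$n_walkers, log_post, rel_scale = 2e-2)
  burn <- ensemble_mcmc(log_post, init, n_steps = config$n_burn)
  last <- burn$samples[dim(burn$samples)[1], , ]
  run <- ensemble_mcmc(log_post, last, n_steps = config$n_keep * config$thin,
                       thin = config$thin)
  flat <- flatten_chain(run$samples, par_names)
  samples <- tibble::as_tibble(as.data.frame(flat))
  samples$lp <- as.vector(t(run$log_prob))
  if (run$acceptance < 0.05) {
    warn(sprintf("low MCMC acceptance (%.1f%%); samples returned but inspect convergence.",
                 100 * run$acceptance))
  }
  new_phen_fit(samples, par_names, counts, kind, mode = "full", fixed = NULL,
               acceptance = run$acceptance,
               ess = setNames(ensemble_ess(run$samples), par_names),
               config = c(config, seed = as.integer(seed)))
}

#' Fit the constrained satellite mode (breeding pairs and fledging success)
#'
#' With sparse late-season counts (as few as six points between September
#' and December) the full model is not identifiable, so every parameter
#' except `BP` and `F` is fixed to supplied defaults, and the arrival date
#' is anchored astronomically: `t0` is chosen so the female return
#' (`t0 + m + b`) falls `return_offset` days after the first sunrise after
#' midwinter at the site.
#'
#' @param counts Data frame with `day`/`date` and `count` of *total*
#'   individuals (adults + chicks).
#' @param site A [colony_site()].
#' @param season_year Calendar year of the season start (March 1); also the
#'   sunrise year.
#' @param defaults A [phenology_params()] set providing the fixed
#'   parameters; ships as [phenology_preset()].
#' @param return_offset Days between first midwinter sunrise and female
#'   return (default 27.4).
#' @param config MCMC configuration ([mcmc_defaults()]; satellite mode needs
#'   far fewer steps than the full fit).
#' @param seed Integer seed (mandatory).
#' @return A `phen_fit` object with free parameters `BP`, `F`, `sigma_log`.
#' @export
fit_satellite <- function(counts, site, season_year,
                          defaults = phenology_preset("pointe-geologie"),
                          return_offset = 27.4,
                          config = mcmc_defaults(n_walkers = 16, n_burn = 300,
                                                 n_keep = 825),
                          seed) {
  stopifnot(inherits(site, "colony_site"), inherits(defaults, "phenology_params"))
  if (missing(seed)) abort("`seed` is mandatory for reproducibility.")
  counts <- normalise_counts(counts, season_year)
  if (nrow(counts) < 3) {
    abort(sprintf("satellite mode needs at least 3 count days, got %d.",
                  nrow(counts)))
  }
  if (nrow(counts) < 5) {
    warn(sprintf("only %d count days; estimates will be weakly constrained.",
                 nrow(counts)))
  }
  sunrise <- first_sunrise_after_midwinter(site, season_year)
  sunrise_doy <- date_to_doy(sunrise, season_year)
  fixed <- unclass(defaults)
  fixed$t0 <- sunrise_doy + return_offset - defaults$m - defaults$b
  box <- phen_par_box()
  par_names <- c("BP", "F", "sigma_log")
  log_post <- function(v) {
    BP <- v[1]; Fv <- v[2]; sig <- v[3]
    if (BP < box["BP", 1] || BP > box["BP", 2]) return(-Inf)
    if (Fv < 0 || Fv > fixed$Hr) return(-Inf)
    if (sig <= 0) return(-Inf)
    p <- fixed; p$BP <- BP; p$F <- Fv
    -sig^2 / (2 * sigma_log_prior_scale()^2) +
      count_log_likelihood(p, counts, sig, kind = "total")
  }
  set.seed(as.integer(seed))
  start <- c(BP = min(max(mean(counts$count) / 1.2, 2100), 14500),
             F = min(0.6, fixed$Hr * 0.9), sigma_log = 0.2)
  opt <- optim(start, function(v) -log_post(v), method = "Nelder-Mead",
               control = list(maxit = 1000))
  if (is.finite(opt$value)) start <- opt$par
  init <- init_ball(start, config$n_walkers, log_post, rel_scale = 5e-2)
  burn <- ensemble_mcmc(log_post, init, n_steps = config$n_burn)
  last <- burn$samples[dim(burn$samples)[1], , ]
  run <- ensemble_mcmc(log_post, last, n_steps = config$n_keep * config$thin,
                       thin = config$thin)
  flat <- flatten_chain(run$samples, par_names)
  samples <- tibble::as_tibble(as.data.frame(flat))
  samples$lp <- as.vector(t(run$log_prob))
  new_phen_fit(samples, par_names, counts, kind = "total", mode = "satellite",
               fixed = fixed, acceptance = run$acceptance,
               ess = setNames(ensemble_ess(run$samples), par_names),
               config = c(config, seed = as.integer(seed),
                          sunrise_doy = sunrise_doy,
                          return_offset = return_offset))
}

# full parameter list for one posterior draw (row of fit$samples)
fit_row_params <- function(fit, row) {
  if (fit$mode == "full") {
    vec_to_par(as.numeric(row[phen_par_names()]))
  } else {
    p <- fit$fixed
    p$BP <- as.numeric(row[["BP"]]); p$F <- as.numeric(row[["F"]])
    structure(p, class = "phenology_params")
  }
}

# posterior-mean parameter set
fit_point_params <- function(fit) {
  means <- colMeans(fit$samples[setdiff(fit$par_names, "sigma_log")])
  if (fit$mode == "full") {
    vec_to_par(as.numeric(means[phen_par_names()]))
  } else {
    p <- fit$fixed
    p$BP <- means[["BP"]]; p$F <- min(means[["F"]], p$Hr)
    structure(p, class = "phenology_params")
  }
}

# derived-quantity samples (closed forms in the parameters)
derived_samples <- function(fit) {
  s <- fit$samples
  grab <- function(nm) {
    if (nm %in% names(s)) s[[nm]] else rep(fit$fixed[[nm]], nrow(s))
  }
  t0 <- grab("t0"); m <- grab("m"); b <- grab("b"); BP <- grab("BP")
  Hr <- grab("Hr"); F_ <- grab("F")
  c_max <- grab("c_max"); c_min <- grab("c_min")
  s_max <- grab("s_max"); s_min <- grab("s_min"); s_fem <- grab("s_fem")
  t_H <- t0 + m + b
  emanc <- t_H + (5 * c_max + s_fem + 3 * s_max + 1) / 2
  fledge <- emanc + 7 * (s_max + s_min) / 2 + 7 * (c_max + c_min) / 2
  tibble::tibble(
    BP = BP, fledged = F_ * BP, dead_chicks = (Hr - F_) * BP,
    lost_eggs = (1 - Hr) * BP, arrival = t0, female_departure = t0 + m,
    female_return = t_H, hatching = t_H, emancipation = emanc,
    fledging = fledge
  )
}

#' Posterior predictive occupancy bands
#'
#' Evaluates the occupancy curve for a thinned set of posterior draws and
#' summarises per day. The reported band combines parameter uncertainty with
#' the lognormal observation noise on the log scale, so about 68% of
#' well-specified observations should fall inside the 1-sigma band.
#'
#' @param object A `phen_fit`.
#' @param days Day-of-year grid (defaults to the season).
#' @param n_draws Number of posterior draws to evaluate.
#' @param ... Unused.
#' @return A tibble: `day`, posterior mean curves `adults`, `chicks`,
#'   `total`, the fitted-series mean `fit_mean`, and multiplicative band
#'   edges `fit_lo`, `fit_hi`.
#' @export
predict.phen_fit <- function(object, days = seq(season_start_doy(),
                                                season_end_doy()),
                             n_draws = 200, ...) {
  s <- object$samples
  idx <- unique(round(seq(1, nrow(s), length.out = min(n_draws, nrow(s)))))
  fl <- count_floor()
  acc <- matrix(NA_real_, length(days), length(idx))
  adults <- chicks <- matrix(0, length(days), length(idx))
  for (j in seq_along(idx)) {
    p <- fit_row_params(object, s[idx[j], ])
    m <- occupancy_matrix(schedule_core(p), days)
    adults[, j] <- rowSums(m[, 1:3, drop = FALSE])
    chicks[, j] <- m[, 4]
    fitted <- if (object$kind == "adults") adults[, j] else
      adults[, j] + chicks[, j]
    acc[, j] <- log(pmax(fitted, fl))
  }
  sig2 <- mean(s$sigma_log[idx]^2)
  mu <- rowMeans(acc)
  band_sd <- sqrt(apply(acc, 1, var) + sig2)
  adult_mean <- rowMeans(adults)
  chick_mean <- rowMeans(chicks)
  tibble::tibble(
    day = days,
    adults = adult_mean, chicks = chick_mean, total = adult_mean + chick_mean,
    fit_mean = exp(mu), fit_lo = exp(mu - band_sd), fit_hi = exp(mu + band_sd)
  )
}

# fraction of fitted observations inside the 1-sigma predictive band
coverage_1sigma <- function(fit, n_draws = 200) {
  pr <- predict(fit, days = fit$data$day, n_draws = n_draws)
  mean(fit$data$count >= pr$fit_lo & fit$data$count <= pr$fit_hi)
}

#' @export
print.phen_fit <- function(x, ...) {
  cat(sprintf("<phen_fit: %s mode, %s counts, %d observations>\n",
              x$mode, x$kind, nrow(x$data)))
  cat(sprintf("  %d posterior samples, acceptance %.2f, min ESS %.0f\n",
              nrow(x$samples), x$acceptance, min(x$ess)))
  bp <- mean(x$samples$BP)
  cat(sprintf("  breeding pairs: %.0f +/- %.0f\n", bp, sd(x$samples$BP)))
  invisible(x)
}

#' Tidy posterior summaries of a phenology fit
#'
#' @param x A `phen_fit`.
#' @param derived Also include derived quantities (breeding outcome counts
#'   and central event days)?
#' @param conf_level Central credible-interval mass.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior sd), `conf.low`, `conf.high`.
#' @export
tidy.phen_fit <- function(x, derived = FALSE, conf_level = 0.95, ...) {
  tab <- x$samples[x$par_names]
  if (derived) {
    der <- derived_samples(x)
    tab <- dplyr::bind_cols(tab, der[setdiff(names(der), names(tab))])
  }
  a <- (1 - conf_level) / 2
  purrr::imap_dfr(as.list(tab), function(v, nm) {
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)))
  })
}

#' One-row fit summary
#'
#' @param x A `phen_fit`.
#' @param ... Unused.
#' @return A tibble with the sample count, acceptance rate, minimum
#'   effective sample size, observation noise, point-estimate R^2 and mean
#'   geometric error against the fitted counts, and the 1-sigma band
#'   coverage.
#' @export
glance.phen_fit <- function(x, ...) {
  p <- fit_point_params(x)
  m <- occupancy_matrix(schedule_core(p), x$data$day)
  pred <- if (x$kind == "adults") rowSums(m[, 1:3, drop = FALSE]) else rowSums(m)
  obs <- x$data$count
  ok <- pred > 0 & obs > 0
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  tibble::tibble(
    n_obs = nrow(x$data), n_samples = nrow(x$samples),
    acceptance = x$acceptance, ess_min = min(x$ess),
    sigma_log = mean(x$samples$sigma_log),
    r_squared = r2,
    geom_error_pct = mean_geometric_error(pred[ok], obs[ok]),
    coverage_1sigma = coverage_1sigma(x)
  )
}

#' Full posterior report
#'
#' @param object A `phen_fit`.
#' @param ... Unused.
#' @return A list of class `phen_fit_summary`: `parameters` (tidy table),
#'   `derived` (tidy table of derived quantities), `fit` (glance row).
#' @export
summary.phen_fit <- function(object, ...) {
  der <- derived_samples(object)
  der_tab <- purrr::imap_dfr(as.list(der), function(v, nm) {
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v))
  })
  structure(list(parameters = tidy(object), derived = der_tab,
                 fit = glance(object)),
            class = "phen_fit_summary")
}

#' @export
print.phen_fit_summary <- function(x, ...) {
  cat("Posterior parameter summary:\n")
  print(as.data.frame(x$parameters), digits = 4, row.names = FALSE)
  cat("\nDerived quantities:\n")
  print(as.data.frame(x$derived), digits = 4, row.names = FALSE)
  cat("\nFit diagnostics:\n")
  print(as.data.frame(x$fit), digits = 4, row.names = FALSE)
  invisible(x)
}
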