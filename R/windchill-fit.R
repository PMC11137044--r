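# Calibration of the five windchill parameters from paired density/weather
# observations. Density errors are multiplicative, so the likelihood is
# lognormal with a jointly-estimated log-scale sd (half-normal prior);
# parameter priors are uniform on wide physical ranges (wind cools, sun
# warms). Walkers start from the log-linear regression of density on the
# four meteorological variables, the standard exploratory estimate of the
# sigmoid's tail slopes.

wc_par_names <- function() c("c_W", "c_R", "c_H", "T_c", "b_0", "sigma_log")

wc_par_box <- function() {
  rbind(
    c_W = c(-5, 0), c_R = c(0, 0.1), c_H = c(-0.5, 0.5),
    T_c = c(-60, 10), b_0 = c(1e-3, 20)
  )
}

wc_log_post_factory <- function(data, rho_max) {
  box <- wc_par_box()
  lo <- box[, 1]; hi <- box[, 2]
  fl <- 1e-4  # animals/m2 floor
  function(v) {
    if (any(v[1:5] < lo) || any(v[1:5] > hi) || v[6] <= 0) return(-Inf)
    p <- list(c_W = v[1], c_R = v[2], c_H = v[3], T_c = v[4], b_0 = v[5],
              rho_max = rho_max)
    ta <- t_apparent_num(data$temp_c, data$wind_ms, data$rad_wm2, data$rh_pct, p)
    rho <- density_num(ta, p)
    -v[6]^2 / (2 * sigma_log_prior_scale()^2) +
      sum(dnorm(log(pmax(data$density, fl)), log(pmax(rho, fl)), v[6],
                log = TRUE))
  }
}

# starting guess from the log-linear regression of density on weather
wc_regression_init <- function(data, rho_max) {
  fit <- tryCatch(
    lm(log(pmax(density, 1e-4)) ~ temp_c + wind_ms + rad_wm2 + rh_pct,
       data = data),
    error = function(e) NULL)
  start <- c(c_W = -1, c_R = 0.01, c_H = -0.01, T_c = -20, b_0 = 5,
             sigma_log = 0.3)
  if (!is.null(fit)) {
    cf <- coef(fit)
    if (all(is.finite(cf)) && cf["temp_c"] < 0) {
      b0 <- -1 / cf["temp_c"]
      start["b_0"] <- min(max(b0, 0.5), 19)
      start["c_W"] <- min(max(cf["wind_ms"] / cf["temp_c"], -4.9), -1e-4)
      start["c_R"] <- min(max(cf["rad_wm2"] / cf["temp_c"], 1e-5), 0.099)
      start["c_H"] <- min(max(cf["rh_pct"] / cf["temp_c"], -0.49), 0.49)
      start["T_c"] <- min(max(start["b_0"] * (cf["(Intercept)"] - log(rho_max)),
                              -59), 9)
    }
  }
  start
}

#' Fit the windchill density model
#'
#' Bayesian calibration of (`c_W`, `c_R`, `c_H`, `T_c`, `b_0`) plus the
#' lognormal observation sd from paired density and weather observations,
#' with `rho_max` fixed at the hexagonal packing limit.
#'
#' @param data Data frame with columns `density` (animals/m2, > 0) and the
#'   weather columns `temp_c`, `wind_ms`, `rad_wm2`, `rh_pct`. Densities are
#'   typically `count / area` with counts linearly interpolated to the image
#'   times ([interpolate_counts()]).
#' @param rho_max Saturation density (animals/m2).
#' @param config MCMC configuration ([mcmc_defaults()]).
#' @param seed Integer seed (mandatory).
#' @return An object of class `windchill_fit` with posterior `samples`,
#'   acceptance rate and ESS; see [tidy.windchill_fit()],
#'   [glance.windchill_fit()] and [windchill_point_params()].
#' @export
fit_windchill <- function(data, rho_max = hexagonal_packing_density(0.3),
                          config = mcmc_defaults(n_walkers = 24, n_burn = 600,
                                                 n_keep = 550),
                          seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducibility.")
  data <- tibble::as_tibble(data)
  check_weather_frame(data)
  if (!"density" %in% names(data)) abort("`data` needs a `density` column.")
  if (any(data$density <= 0)) abort("densities must be > 0.")
  if (nrow(data) < 20) {
    warn(sprintf("only %d paired observations; the fit expects >= 20.", nrow(data)))
  }
  spreads <- vapply(data[c("temp_c", "wind_ms", "rad_wm2", "rh_pct")], sd,
                    numeric(1))
  if (any(spreads < 1e-8)) {
    warn(paste0("near-constant weather variable(s): ",
                paste(names(spreads)[spreads < 1e-8], collapse = ", "),
                "; the corresponding coefficients are not identifiable."))
  }
  log_post <- wc_log_post_factory(data, rho_max)
  set.seed(as.integer(seed))
  start <- wc_regression_init(data, rho_max)
  if (!is.finite(log_post(start))) {
    start <- c(c_W = -1, c_R = 0.01, c_H = -0.01, T_c = -20, b_0 = 5,
               sigma_log = 0.3)
  }
  opt <- optim(start, function(v) -log_post(v), method = "Nelder-Mead",
               control = list(maxit = 2000))
  if (is.finite(opt$value)) start <- opt$par
  init <- init_ball(start, config$n_walkers, log_post, rel_scale = 5e-2)
  burn <- ensemble_mcmc(log_post, init, n_steps = config$n_burn)
  last <- burn$samples[dim(burn$samples)[1], , ]
  run <- ensemble_mcmc(log_post, last, n_steps = config$n_keep * config$thin,
                       thin = config$thin)
  flat <- flatten_chain(run$samples, wc_par_names())
  samples <- tibble::as_tibble(as.data.frame(flat))
  samples$lp <- as.vector(t(run$log_prob))
  structure(list(samples = samples, par_names = wc_par_names(), data = data,
                 rho_max = rho_max, acceptance = run$acceptance,
                 ess = setNames(ensemble_ess(run$samples), wc_par_names()),
                 config = c(config, seed = as.integer(seed))),
            class = "windchill_fit")
}

#' Posterior-mean windchill parameters
#'
#' @param fit A `windchill_fit`.
#' @return A [windchill_params()] object from the posterior means.
#' @export
windchill_point_params <- function(fit) {
  stopifnot(inherits(fit, "windchill_fit"))
  m <- colMeans(fit$samples[c("c_W", "c_R", "c_H", "T_c", "b_0")])
  windchill_params(c_W = m[["c_W"]], c_R = m[["c_R"]], c_H = m[["c_H"]],
                   T_c = m[["T_c"]], b_0 = m[["b_0"]], rho_max = fit$rho_max)
}

#' @export
print.windchill_fit <- function(x, ...) {
  cat(sprintf("<windchill_fit: %d observations, %d posterior samples>\n",
              nrow(x$data), nrow(x$samples)))
  cat(sprintf("  acceptance %.2f, min ESS %.0f\n", x$acceptance, min(x$ess)))
  invisible(x)
}

#' @rdname fit_windchill
#' @param x A `windchill_fit`.
#' @param conf_level Central credible-interval mass.
#' @param ... Unused.
#' @export
tidy.windchill_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  purrr::imap_dfr(as.list(x$samples[x$par_names]), function(v, nm) {
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)))
  })
}

#' @rdname fit_windchill
#' @export
glance.windchill_fit <- function(x, ...) {
  p <- windchill_point_params(x)
  pred <- predict_density(x$data, p)$density
  obs <- x$data$density
  tibble::tibble(
    n_obs = nrow(x$data), n_samples = nrow(x$samples),
    acceptance = x$acceptance, ess_min = min(x$ess),
    sigma_log = mean(x$samples$sigma_log),
    r_squared = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
    geom_error_pct = mean_geometric_error(pred, obs)
  )
}
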