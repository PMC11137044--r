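mid_params <- function() {
  phenology_params(t0 = 100, dt0 = 7, m = 35, b = 75, db = 8, BP = 8000,
                   NB = 0.5, Hr = 0.6, F = 0.4, c_max = 3, c_min = 2,
                   s_max = 12, s_min = 6, s_fem = 8)
}

test_that("the prior is a uniform box with ordering constraints", {
  expect_true(is.finite(phenology_log_prior(mid_params())))
  v <- unlist(unclass(mid_params()))
  v["b"] <- 120
  expect_identical(phenology_log_prior(v), -Inf)
  v <- unlist(unclass(mid_params()))
  v["s_min"] <- 15; v["s_max"] <- 12
  expect_identical(phenology_log_prior(v), -Inf)
  v <- unlist(unclass(mid_params()))
  v["F"] <- 0.9
  expect_identical(phenology_log_prior(v), -Inf)   # F > Hr
  expect_identical(phenology_log_prior(mid_params(), sigma_log = -1), -Inf)
  expect_true(is.finite(phenology_log_prior(mid_params(), sigma_log = 0.2)))
})

test_that("the likelihood peaks at the generating curve and obeys the closed-form shift", {
  p <- mid_params()
  days <- seq(70, 400, by = 7)
  model <- occupancy(p, days = days)$adults
  obs <- tibble::tibble(day = days, count = model)
  ll0 <- count_log_likelihood(p, obs, 0.1, kind = "adults")
  # any parameter perturbation lowers the likelihood of exact data
  for (nm in c("t0", "m", "BP", "Hr")) {
    q <- unclass(p)
    q[[nm]] <- q[[nm]] * 1.05
    expect_lt(count_log_likelihood(q, obs, 0.1, kind = "adults"), ll0)
  }
  # doubling exact observations costs (log 2)^2 / (2 sigma^2) per point
  obs2 <- tibble::tibble(day = days, count = 2 * model)
  n_pos <- sum(model > colonyphen:::count_floor())
  expect_equal(ll0 - count_log_likelihood(p, obs2, 0.1, kind = "adults"),
               n_pos * log(2)^2 / (2 * 0.1^2), tolerance = 1e-6)
  # infinite noise flattens the likelihood across parameter sets
  q <- unclass(p); q$BP <- 12000
  expect_lt(abs(count_log_likelihood(p, obs, 1e4, kind = "adults") -
                  count_log_likelihood(q, obs, 1e4, kind = "adults")), 1e-4)
})

test_that("geometric error matches its defining examples and symmetry", {
  expect_equal(geometric_error(1.25, 1), 25)
  expect_equal(geometric_error(1, 1), 0)
  expect_equal(geometric_error(0.5, 1), 100)   # 2-fold underestimate
  x <- c(1.3, 0.4, 2.2); y <- c(1.1, 0.5, 2.2)
  expect_equal(geometric_error(x, y), geometric_error(y, x))
  expect_equal(mean_geometric_error(x, y),
               (exp(mean(abs(log(x / y)))) - 1) * 100)
  expect_error(geometric_error(-1, 1), "positive")
})

test_that("satellite mode recovers BP and F from noiseless sparse counts", {
  site <- pg_site()
  defaults <- phenology_preset("pointe-geologie")
  sunrise <- first_sunrise_after_midwinter(site, 2019)
  t0 <- as.numeric(format(sunrise, "%j")) + 27.4 - defaults$m - defaults$b
  truth <- unclass(defaults); truth$t0 <- t0; truth$BP <- 6000; truth$F <- 0.5
  truth <- structure(truth, class = "phenology_params")
  days <- c(275, 290, 305, 320, 335, 350)
  obs <- tibble::tibble(day = days, count = occupancy(truth, days = days)$total)
  # the noiseless limit is a sigma -> 0 funnel: a wider, longer ensemble is
  # needed to settle into the exact-fit mode
  fit <- fit_satellite(obs, site, 2019, defaults = defaults, seed = 5,
                       config = tiny_mcmc(32, 800, 400))
  expect_lt(abs(mean(fit$samples$BP) - 6000) / 6000, 0.05)
  expect_lt(abs(mean(fit$samples$F) - 0.5), 0.05)
  # the anchoring rule: implied female return = sunrise + offset
  expect_equal(fit$fixed$t0 + defaults$m + defaults$b,
               as.numeric(format(sunrise, "%j")) + 27.4)
})

test_that("satellite mode refuses starved inputs and warns when thin", {
  site <- pg_site()
  obs2 <- tibble::tibble(day = c(280, 300), count = c(4000, 4100))
  expect_error(fit_satellite(obs2, site, 2019, seed = 1), "at least 3")
  obs4 <- tibble::tibble(day = c(280, 300, 320, 340), count = 4000 + 1:4 * 50)
  expect_warning(
    fit_satellite(obs4, site, 2019, seed = 1, config = tiny_mcmc(8, 40, 40)),
    "weakly constrained")
})

test_that("fits are reproducible given the seed", {
  site <- pg_site()
  days <- c(275, 295, 315, 335, 350)
  obs <- tibble::tibble(day = days, count = c(3000, 3600, 3900, 3500, 2800))
  f1 <- fit_satellite(obs, site, 2019, seed = 7, config = tiny_mcmc(8, 60, 80))
  f2 <- fit_satellite(obs, site, 2019, seed = 7, config = tiny_mcmc(8, 60, 80))
  expect_identical(f1$samples, f2$samples)
})

test_that("summaries are recomputable from the exported samples", {
  site <- pg_site()
  days <- c(275, 295, 315, 335, 350)
  obs <- tibble::tibble(day = days, count = c(3000, 3600, 3900, 3500, 2800))
  fit <- fit_satellite(obs, site, 2019, seed = 7, config = tiny_mcmc(8, 60, 120))
  tt <- tidy(fit)
  expect_equal(tt$estimate[tt$term == "BP"], mean(fit$samples$BP))
  expect_equal(tt$std.error[tt$term == "F"], stats::sd(fit$samples$F))
  su <- summary(fit)
  expect_equal(su$derived$estimate[su$derived$term == "fledged"],
               mean(fit$samples$F * fit$samples$BP))
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("the 1-sigma predictive band is roughly calibrated on well-specified data", {
  site <- pg_site()
  defaults <- phenology_preset("pointe-geologie")
  sunrise_doy <- as.numeric(format(first_sunrise_after_midwinter(site, 2019), "%j"))
  truth <- unclass(defaults)
  truth$t0 <- sunrise_doy + 27.4 - defaults$m - defaults$b   # anchored arrival
  truth <- structure(truth, class = "phenology_params")
  days <- seq(250, 400, by = 7)
  set.seed(14)
  exact <- occupancy(truth, days = days)$total
  obs <- tibble::tibble(day = days, count = exact * exp(rnorm(length(days), 0, 0.1)))
  obs <- obs[obs$count > 1, ]
  fit <- fit_satellite(obs, site, 2019, defaults = defaults, seed = 2,
                       config = tiny_mcmc(16, 150, 200))
  cov <- colonyphen:::coverage_1sigma(fit)
  expect_gt(cov, 0.45)
  expect_lte(cov, 1)
})
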