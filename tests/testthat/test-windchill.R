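test_that("apparent temperature is the stated linear combination", {
  p0 <- wc_plain()
  expect_equal(apparent_temperature(weather_row(temp_c = -20), p0)$t_apparent, -20)
  p_w <- windchill_params(c_W = -1, c_R = 0, c_H = 0, T_c = -10, b_0 = 4)
  expect_equal(
    apparent_temperature(weather_row(temp_c = -10, wind_ms = 5), p_w)$t_apparent,
    -15)
  p_r <- windchill_params(c_W = 0, c_R = 0.02, c_H = 0, T_c = -10, b_0 = 4)
  expect_equal(
    apparent_temperature(weather_row(temp_c = 0, rad_wm2 = 100), p_r)$t_apparent,
    2)
  expect_error(apparent_temperature(weather_row(rh_pct = 120), p0), "rh_pct")
  expect_error(apparent_temperature(weather_row(wind_ms = -1), p0), "wind_ms")
})

test_that("density sigmoid: half-max at T_c, closed-form quartile, limits, monotone", {
  p <- wc_plain(T_c = -12, b_0 = 3)
  rho_max <- hexagonal_packing_density(0.3)
  expect_equal(density_from_apparent_temperature(p$T_c, p), rho_max / 2)
  expect_equal(density_from_apparent_temperature(p$T_c + p$b_0 * log(3), p),
               rho_max / 4)
  expect_equal(density_from_apparent_temperature(-1e4, p), rho_max,
               tolerance = 1e-12)
  expect_lt(density_from_apparent_temperature(1e4, p), 1e-12)
  ta <- seq(-60, 30, by = 0.5)
  expect_true(all(diff(density_from_apparent_temperature(ta, p)) < 0))
})

test_that("hexagonal packing density follows the closed form and scaling", {
  expect_identical(hexagonal_packing_density(0.3), 12.8)
  expect_equal(hexagonal_packing_density(1),
               signif((pi / (2 * sqrt(3))) / (pi / 4), 3))
  expect_equal(hexagonal_packing_density(0.6),
               signif(hexagonal_packing_density(0.3) / 4, 3), tolerance = 1e-2)
  expect_error(hexagonal_packing_density(0), "positive")
})

test_that("counts from area multiply and compose back to density", {
  expect_equal(counts_from_area(1000, 0.93), 930)
  expect_equal(counts_from_area(0, 5), 0)
  expect_error(counts_from_area(-1, 1), ">= 0")
  # composition identity on consistent observations
  p <- wc_plain()
  rho <- density_from_apparent_temperature(c(-30, -10, 5), p)
  area <- c(200, 1000, 4000)
  n <- counts_from_area(area, rho)
  expect_equal(n / area, rho)
})

test_that("count interpolation is piecewise linear and refuses extrapolation", {
  counts <- tibble::tibble(day = c(0, 10, 20), count = c(100, 200, 100))
  expect_equal(interpolate_counts(counts, 5)$count, 150)
  expect_equal(interpolate_counts(counts, 15)$count, 150)
  expect_equal(interpolate_counts(counts, 10)$count, 200)  # identity at a knot
  expect_error(interpolate_counts(counts, 25), "extrapolate")
  expect_error(interpolate_counts(counts[1, ], 0), "at least 2")
})

test_that("same-day predictions are averaged, singletons pass through", {
  ts <- as.POSIXct("2019-10-01 00:00", tz = "UTC") + c(0, 3600, 7200, 86400)
  df <- tibble::tibble(timestamp = ts, count = c(0, 0, 300, 500))
  out <- daily_average_counts(df)
  expect_equal(out$count, c(100, 500))
  expect_equal(out$n_obs, c(3L, 1L))
})

test_that("windchill calibration is self-consistent on noiseless data and collapses under permutation", {
  wc_true <- windchill_preset()
  spec <- generator_spec(seed = 4)
  days <- seq(250, 360, length.out = 60) + 0.4
  wx <- generate_weather(spec, days)
  rho <- predict_density(wx, wc_true)$density
  dat <- dplyr::mutate(wx, density = rho)
  fit <- fit_windchill(dat, seed = 2, config = tiny_mcmc(24, 300, 150))
  expect_gt(glance(fit)$r_squared, 0.99)
  # permuted densities carry no weather signal
  set.seed(99)
  dat_perm <- dplyr::mutate(dat, density = sample(density))
  fit_perm <- fit_windchill(dat_perm, seed = 2, config = tiny_mcmc(24, 300, 150))
  expect_lt(glance(fit_perm)$r_squared, 0.2)
})

test_that("constant weather triggers a non-identifiability warning", {
  set.seed(1)
  dat <- tibble::tibble(temp_c = -10, wind_ms = 5, rad_wm2 = 100, rh_pct = 70,
                        density = exp(rnorm(25, 0, 0.1)))
  expect_warning(
    fit_windchill(dat, seed = 1, config = tiny_mcmc(24, 50, 50)),
    "identifiable")
})
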