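test_that("zero-noise counts equal the occupancy curve exactly", {
  spec <- generator_spec(noise_count = 0, seed = 1)
  counts <- generate_counts(spec)
  exact <- occupancy(spec$phenology, days = counts$day)
  expect_equal(counts$adults, exact$adults)
  expect_equal(counts$chicks, exact$chick)
  expect_equal(counts$total, exact$total)
})

test_that("generated noise is multiplicative at the configured level", {
  spec <- generator_spec(noise_count = 0.10, seed = 6)
  counts <- generate_counts(spec)
  exact <- occupancy(spec$phenology, days = counts$day)
  keep <- exact$adults > 100
  logr <- log(counts$adults[keep] / exact$adults[keep])
  expect_equal(stats::sd(logr), 0.10, tolerance = 0.35)
  expect_lt(abs(mean(logr)), 0.05)
})

test_that("all generator streams are reproducible from the spec and seed", {
  spec <- generator_spec(seed = 12)
  days <- seq(250, 300, by = 2.5)
  expect_identical(generate_weather(spec, days), generate_weather(spec, days))
  expect_identical(generate_counts(spec)$adults, generate_counts(spec)$adults)
  a1 <- generate_areas(spec, days)
  a2 <- generate_areas(spec, days)
  expect_identical(a1$area_m2, a2$area_m2)
  spec2 <- generator_spec(seed = 13)
  expect_false(identical(generate_weather(spec2, days)$temp_c,
                         generate_weather(spec, days)$temp_c))
})

test_that("generated weather respects physical bounds", {
  spec <- generator_spec(seed = 3, weather = list(rh_sd = 40, wind_sd = 8))
  wx <- generate_weather(spec, seq(60, 424, by = 0.5))
  expect_true(all(wx$rh_pct >= 0 & wx$rh_pct <= 100))
  expect_true(all(wx$wind_ms >= 0))
  expect_true(all(wx$rad_wm2 >= 0))
  # polar night: no radiation at midwinter, some in midsummer
  expect_equal(max(wx$rad_wm2[wx$day > 170 & wx$day < 180]), 0)
  expect_gt(max(wx$rad_wm2[wx$day > 290]), 50)
})

test_that("zero weather noise yields deterministic seasonal curves", {
  quiet <- list(temp_sd = 0, wind_sd = 0, rad_sd = 0, rh_sd = 0)
  w1 <- generate_weather(generator_spec(seed = 1, weather = quiet), 100:150)
  w2 <- generate_weather(generator_spec(seed = 99, weather = quiet), 100:150)
  expect_equal(w1$temp_c, w2$temp_c)   # seeds irrelevant without noise
  expect_equal(w1$wind_ms, w2$wind_ms)
})

test_that("areas invert the windchill model and skip empty-colony times", {
  spec <- generator_spec(noise_area = 0, seed = 8)
  days <- seq(250, 300, by = 5) + 0.5
  areas <- generate_areas(spec, days)
  wx <- attr(areas, "weather")
  rho <- predict_density(wx, spec$windchill)$density
  n_back <- counts_from_area(areas$area_m2, rho)
  expect_equal(n_back, attr(areas, "truth_counts"), tolerance = 1e-12)
  # times before arrival have (almost) nobody present: tiny N, finite area
  early <- generate_areas(spec, c(70.5, 250.5))
  expect_equal(nrow(early), 2)
})
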