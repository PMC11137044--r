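test_that("solar declination hits the solstice extrema and equinox zero", {
  expect_equal(solar_declination(as.Date("2019-06-21")), 23.44, tolerance = 0.02)
  expect_equal(solar_declination(as.Date("2019-12-22")), -23.44, tolerance = 0.02)
  expect_lt(abs(solar_declination(as.Date("2019-03-20"))), 0.7)
  # always inside the tropic band, any day of any year
  days <- as.Date("2015-01-01") + 0:1500
  d <- solar_declination(days)
  expect_true(all(d >= -23.45 & d <= 23.45))
})

test_that("sites without polar night get the solstice date back", {
  eq <- colony_site("equator", 0, 0)
  expect_equal(format(first_sunrise_after_midwinter(eq, 2019), "%m"), "06")
  mild <- colony_site("mild", -45, 30)
  expect_lt(as.numeric(format(first_sunrise_after_midwinter(mild, 2019), "%j")), 176)
})

test_that("first sunrise is monotone in latitude and bounded by the equinox", {
  lats <- c(-60, -67, -70, -75, -78)
  dates <- vapply(lats, function(la) {
    as.numeric(format(first_sunrise_after_midwinter(
      colony_site("s", la, 140), 2019), "%j"))
  }, numeric(1))
  expect_true(all(diff(dates) >= 0))       # more southerly never earlier
  solstice_doy <- as.numeric(format(as.Date("2019-06-21"), "%j"))
  equinox_doy <- as.numeric(format(as.Date("2019-09-23"), "%j"))
  expect_true(all(dates >= solstice_doy & dates <= equinox_doy))
})

test_that("site constructor enforces coordinate ranges", {
  expect_error(colony_site("x", 10, 0), "southern")
  expect_error(colony_site("x", -200, 0), "-90")
  expect_error(colony_site("x", -60, 500), "-180")
})
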