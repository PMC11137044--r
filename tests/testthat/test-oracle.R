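# The individual-based simulation and the analytic CDF sum are two
# independent routes to the same expectation; binomial sampling error is the
# only allowed difference.

oracle_check <- function(p, n_pairs, seed) {
  sim <- agent_oracle(p, n_pairs = n_pairs, seed = seed)
  ana <- occupancy(p)
  scale <- n_pairs / p$BP
  for (coh in c("female", "male", "non_breeder", "chick")) {
    n_coh <- if (coh == "non_breeder") round(p$NB * n_pairs) else n_pairs
    if (n_coh == 0) next
    expected <- ana[[coh]] * scale
    pfrac <- pmin(pmax(expected / n_coh, 0), 1)
    se <- sqrt(n_coh * pfrac * (1 - pfrac))
    dev <- abs(sim[[coh]] - expected)
    # mean absolute deviation per day within 3 binomial SEs (+1 animal for
    # integer discreteness)
    expect_lt(mean(dev), mean(3 * se + 1))
    # per-day excursions beyond 3 SE + 1 must be rare (correlated days share
    # one bird's offset, so a few are expected)
    expect_lt(mean(dev > 3 * se + 1), 0.02)
  }
}

test_that("agent simulation matches analytic occupancy within binomial error", {
  oracle_check(phenology_preset("pointe-geologie"), n_pairs = 2e4, seed = 11)
  set.seed(5)
  for (p in random_phenology_params(2)) oracle_check(p, n_pairs = 2e4, seed = 12)
})

test_that("the oracle is bitwise reproducible from its seed", {
  p <- phenology_preset("pointe-geologie")
  a <- agent_oracle(p, 500, seed = 3)
  b <- agent_oracle(p, 500, seed = 3)
  expect_identical(a, b)
  c <- agent_oracle(p, 500, seed = 4)
  expect_false(identical(a, c))
})

test_that("oracle counts are non-negative integers with sane totals", {
  p <- phenology_preset("atka-bay")
  sim <- agent_oracle(p, 1000, seed = 8)
  counts <- as.matrix(sim[, c("female", "male", "non_breeder", "chick")])
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_lte(max(sim$female), 1000)
  expect_lte(max(sim$chick), 1000)
})
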