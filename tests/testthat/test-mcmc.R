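test_that("the ensemble sampler recovers a correlated Gaussian target", {
  S_inv <- solve(matrix(c(1, 0.8, 0.8, 2), 2))
  mu <- c(3, -1)
  lp <- function(x) -0.5 * drop(t(x - mu) %*% S_inv %*% (x - mu))
  set.seed(42)
  init <- matrix(rnorm(2 * 24, sd = 0.2), 24, 2) + rep(mu, each = 24)
  out <- ensemble_mcmc(lp, init, n_steps = 1500)
  flat <- colonyphen:::flatten_chain(out$samples[501:1500, , , drop = FALSE])
  expect_equal(colMeans(flat), mu, tolerance = 0.1)
  expect_equal(stats::sd(flat[, 2]), sqrt(2), tolerance = 0.12)
  expect_equal(stats::cor(flat[, 1], flat[, 2]), 0.8 / sqrt(2), tolerance = 0.12)
  expect_gt(out$acceptance, 0.2)
})

test_that("sampling is deterministic under a fixed RNG state", {
  lp <- function(x) -sum(x^2) / 2
  run <- function() {
    set.seed(9)
    init <- matrix(rnorm(3 * 12, sd = 0.1), 12, 3)
    ensemble_mcmc(lp, init, n_steps = 50)
  }
  expect_identical(run()$samples, run()$samples)
})

test_that("bad walker setups are rejected", {
  lp <- function(x) if (any(x < 0)) -Inf else -sum(x)
  expect_error(ensemble_mcmc(lp, matrix(1, 7, 2), 10), "even")
  expect_error(ensemble_mcmc(lp, matrix(-1, 8, 2), 10), "non-finite")
  expect_warning(ensemble_mcmc(lp, matrix(1, 2, 2), 5), "recommended")
})
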