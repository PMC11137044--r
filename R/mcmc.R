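# Affine-invariant ensemble MCMC (Goodman & Weare stretch move).
#
# The two fitting problems in this package (windchill density and the
# phenological occupancy model) have box-constrained, moderately correlated
# posteriors of 3-15 dimensions; the stretch move needs no proposal tuning
# and is invariant to linear reparameterisation, which suits both. Walkers
# are updated in two half-ensembles so each move conditions only on the
# complementary half.

#' Affine-invariant ensemble sampler
#'
#' Samples from an unnormalised log-density using the stretch move. This is
#' the workhorse behind [fit_windchill()], [fit_phenology()] and
#' [fit_satellite()]; it is exported so the samplers are testable against
#' known targets.
#'
#' @param log_prob Function taking a parameter vector, returning a log
#'   density (may be `-Inf`).
#' @param init Numeric matrix `n_walkers x n_dim` of starting positions;
#'   every row must have finite `log_prob`.
#' @param n_steps Number of ensemble steps to run.
#' @param a Stretch scale parameter (> 1); 2 is the standard choice.
#' @param thin Keep every `thin`-th step.
#' @param progress Unused placeholder for API stability.
#' @return A list with `samples` (array `kept_steps x n_walkers x n_dim`),
#'   `log_prob` (matrix `kept_steps x n_walkers`), and `acceptance` (overall
#'   acceptance fraction). Reproducible under `set.seed()`.
#' @examples
#' lp <- function(x) -sum(x^2) / 2
#' set.seed(1)
#' init <- matrix(rnorm(20 * 2, sd = 0.1), 20, 2)
#' fit <- ensemble_mcmc(lp, init, n_steps = 200)
#' @export
ensemble_mcmc <- function(log_prob, init, n_steps, a = 2, thin = 1,
                          progress = FALSE) {
  if (!is.matrix(init)) abort("`init` must be a matrix (walkers x dims).")
  n_walkers <- nrow(init)
  n_dim <- ncol(init)
  if (n_walkers < 2 * n_dim) {
    warn(sprintf("only %d walkers for %d dimensions; >= %d recommended.",
                 n_walkers, n_dim, 2 * n_dim))
  }
  if (n_walkers %% 2 != 0) abort("`n_walkers` must be even.")
  pos <- init
  lp <- apply(pos, 1, log_prob)
  if (any(!is.finite(lp))) {
    abort(sprintf("%d of %d walker starting positions have non-finite log_prob.",
                  sum(!is.finite(lp)), n_walkers))
  }
  kept <- floor(n_steps / thin)
  samples <- array(NA_real_, dim = c(kept, n_walkers, n_dim))
  lp_out <- matrix(NA_real_, kept, n_walkers)
  halves <- list(seq_len(n_walkers / 2), seq_len(n_walkers / 2) + n_walkers / 2)
  n_acc <- 0L
  k <- 0L
  for (step in seq_len(n_steps)) {
    for (h in 1:2) {
      move <- halves[[h]]
      other <- halves[[3 - h]]
      nh <- length(move)
      # z ~ g(z) prop. 1/sqrt(z) on [1/a, a]
      z <- (1 / a) * (1 + (a - 1) * runif(nh))^2
      partner <- other[sample.int(length(other), nh, replace = TRUE)]
      prop <- pos[partner, , drop = FALSE] +
        z * (pos[move, , drop = FALSE] - pos[partner, , drop = FALSE])
      lp_prop <- apply(prop, 1, log_prob)
      log_ratio <- (n_dim - 1) * log(z) + lp_prop - lp[move]
      accept <- log(runif(nh)) < log_ratio
      accept[!is.finite(lp_prop)] <- FALSE
      pos[move[accept], ] <- prop[accept, , drop = FALSE]
      lp[move[accept]] <- lp_prop[accept]
      n_acc <- n_acc + sum(accept)
    }
    if (step %% thin == 0) {
      k <- k + 1L
      samples[k, , ] <- pos
      lp_out[k, ] <- lp
    }
  }
  list(samples = samples, log_prob = lp_out,
       acceptance = n_acc / (n_steps * n_walkers))
}

# Flatten an ensemble sample array into a (kept*walkers) x dim matrix.
flatten_chain <- function(samples, par_names = NULL) {
  d <- dim(samples)
  out <- matrix(aperm(samples, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  if (!is.null(par_names)) colnames(out) <- par_names
  out
}

# Crude effective sample size: per-walker mean chain, initial positive
# sequence of autocorrelations, summed over walkers.
ensemble_ess <- function(samples) {
  d <- dim(samples)
  n_steps <- d[1]; n_walkers <- d[2]; n_dim <- d[3]
  vapply(seq_len(n_dim), function(j) {
    chain <- rowMeans(samples[, , j, drop = FALSE][, , 1])
    if (sd(chain) == 0) return(n_steps * n_walkers)
    rho <- acf(chain, lag.max = min(n_steps - 1, 200), plot = FALSE)$acf[-1]
    pos <- which(rho < 0.05)
    cut <- if (length(pos) == 0) length(rho) else pos[1] - 1
    tau <- 1 + 2 * sum(rho[seq_len(cut)])
    n_steps * n_walkers / max(tau, 1)
  }, numeric(1))
}

# Scatter `n_walkers` starting points in a small ball around `center`,
# reflected into finiteness of `log_prob` by resampling.
init_ball <- function(center, n_walkers, log_prob, rel_scale = 1e-2,
                      abs_scale = NULL, max_tries = 200) {
  n_dim <- length(center)
  scale <- abs_scale %||% pmax(abs(center) * rel_scale, 1e-4)
  out <- matrix(NA_real_, n_walkers, n_dim)
  for (i in seq_len(n_walkers)) {
    for (try in seq_len(max_tries)) {
      cand <- center + rnorm(n_dim) * scale
      if (is.finite(log_prob(cand))) {
        out[i, ] <- cand
        break
      }
    }
    if (any(is.na(out[i, ]))) {
      abort("could not find a finite-density starting point near the initial guess.")
    }
  }
  out
}
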