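# Independent oracles used across the suite. These re-derive every density
# and summary from first principles (lgamma/lbeta arithmetic, brute-force
# grids, analytic identities) and must stay independent of the package code
# paths they check.

# --- term-by-term log densities -------------------------------------------

oracle_lbinom <- function(k, n, p) {
  lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
}

oracle_lbeta_density <- function(x, a, b) {
  (a - 1) * log(x) + (b - 1) * log1p(-x) - lbeta(a, b)
}

oracle_lgamma_density <- function(x, shape, rate) {
  shape * log(rate) + (shape - 1) * log(x) - rate * x - lgamma(shape)
}

oracle_log_posterior <- function(omega, kappa, theta, k, n, prior) {
  a <- omega * (kappa - 2) + 1
  b <- (1 - omega) * (kappa - 2) + 1
  sum(oracle_lbinom(k, n, theta)) +
    sum(oracle_lbeta_density(theta, a, b)) +
    oracle_lbeta_density(omega, prior$alpha, prior$beta) +
    oracle_lgamma_density(kappa - prior$kappa_offset,
                          prior$kappa_shape, prior$kappa_rate)
}

# --- dense 2-D grid posterior with theta marginalized analytically --------
# Beta-binomial identity: p(k | omega, kappa) =
#   choose(n, k) * B(a + k, b + n - k) / B(a, b).
grid_posterior_omega <- function(k, n, prior, n_omega = 400, n_kappa = 400) {
  omega <- (seq_len(n_omega) - 0.5) / n_omega
  q <- (seq_len(n_kappa) - 0.5) / n_kappa
  kap_excess <- qgamma(q * 0.9998 + 1e-4, prior$kappa_shape,
                       prior$kappa_rate)
  lp <- matrix(0, n_omega, n_kappa)
  for (j in seq_len(n_kappa)) {
    kappa <- prior$kappa_offset + kap_excess[j]
    a <- omega * (kappa - 2) + 1
    b <- (1 - omega) * (kappa - 2) + 1
    ll <- rep(0, n_omega)
    for (r in seq_along(k)) {
      ll <- ll + lchoose(n[r], k[r]) +
        lbeta(a + k[r], b + n[r] - k[r]) - lbeta(a, b)
    }
    # equal-probability-mass kappa grid: the Gamma prior weight is implicit
    lp[, j] <- ll + dbeta(omega, prior$alpha, prior$beta, log = TRUE)
  }
  w <- exp(lp - max(lp))
  list(omega = omega, post_mean_omega = sum(omega * rowSums(w)) / sum(w))
}

# --- brute-force HDI of an analytic distribution --------------------------
# Exhaustive window scan over an M-point quantile grid of qfun.
grid_hdi_oracle <- function(qfun, mass = 0.95, M = 1e4, ...) {
  p <- (seq_len(M) - 0.5) / M
  x <- qfun(p, ...)
  w <- ceiling(mass * M)
  widths <- x[w:M] - x[1:(M - w + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + w - 1])
}

# --- simple process generators --------------------------------------------

ar1_chain <- function(n, rho, seed) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- rnorm(n - 1, sd = sqrt(1 - rho^2))
  for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  x
}

make_group <- function(k, n = 20, condition = "test", generation = "F1") {
  suppressWarnings(mf_group(condition, generation, k, n))
}

# Fit a scenario's reversal generations and classify its memory.
run_scenario_memory <- function(scenario, seed, band,
                                settings_budget = list(n_chains = 2L,
                                                       n_warmup = 500L,
                                                       n_draws = 2500L,
                                                       target_ess = 300)) {
  truth <- build_trajectory(scenario)
  tab <- simulate_counts(truth, scenario, seed = seed,
                         condition_id = "scen")
  groups <- plate_table_to_groups(tab)
  rev_groups <- Filter(function(g) {
    parse_generation(g$generation)$phase == "reversal"
  }, groups)
  set.seed(seed + 1L)
  fit_seeds <- sample.int(2147483646L, length(rev_groups))
  summaries <- do.call(rbind, lapply(seq_along(rev_groups), function(i) {
    st <- do.call(sampler_settings,
                  c(settings_budget, list(seed = fit_seeds[i])))
    fit <- suppressWarnings(sample_posterior(rev_groups[[i]],
                                             hyper_prior(), st))
    summarize_group(fit)
  }))
  classify_memory(summaries, band)
}
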