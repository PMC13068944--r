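#' Simulation-based calibration of interval coverage
#'
#' Validates the whole inference pipeline against itself: data simulated
#' from the model's own prior must yield credible intervals with nominal
#' coverage. Each replicate draws (omega, kappa, theta, counts) from the
#' prior predictive, fits the posterior, and checks whether the per-plate
#' theta HDIs (and the omega HDI) contain the generating truth. Replicates
#' whose fit fails the convergence contract are excluded and counted.
#'
#' @param prior an [hyper_prior()].
#' @param plates,animals design of each simulated group.
#' @param settings [sampler_settings()] used for every fit; a reduced draw
#'   budget (with a correspondingly reduced `target_ess`) keeps the run
#'   short while HDI endpoints stay stable.
#' @param n_replicates number of prior-predictive replicates (>= 100).
#' @param mass nominal interval mass (default 0.95).
#' @param seed master seed; per-replicate simulation and sampler seeds
#'   derive from it.
#' @return A list: `theta_coverage` and `omega_coverage` (fractions in
#'   \[0,1\]), `n_theta` (number of (replicate, plate) pairs scored),
#'   `n_used`, `n_excluded` (non-convergent fits), `mass`.
#' @export
sbc_coverage <- function(prior = hyper_prior(), plates = 10L, animals = 20L,
                         settings = sampler_settings(
                           n_chains = 2L, n_warmup = 500L, n_draws = 2500L,
                           target_ess = 300),
                         n_replicates = 500L, mass = 0.95, seed = 1L) {
  stopifnot(inherits(prior, "mf_prior"), inherits(settings, "mf_settings"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 100L) stop("n_replicates must be >= 100")
  set.seed(as.integer(seed))
  rep_seeds <- matrix(sample.int(2147483646L, 2L * n_replicates),
                      ncol = 2L)
  theta_hits <- 0L
  theta_tot <- 0L
  omega_hits <- 0L
  n_excluded <- 0L
  for (i in seq_len(n_replicates)) {
    sim <- simulate_prior_predictive(prior, plates, animals,
                                     seed = rep_seeds[i, 1L])
    grp <- suppressWarnings(
      mf_group("sbc", "F1", sim$table$n_eu, sim$table$n_animals)
    )
    st <- settings
    st$seed <- rep_seeds[i, 2L]
    fit <- withCallingHandlers(
      sample_posterior(grp, prior, st),
      mf_convergence_warning = function(w) invokeRestart("muffleWarning")
    )
    if (!fit$converged) {
      n_excluded <- n_excluded + 1L
      next
    }
    for (r in seq_len(plates)) {
      h <- hdi(pool_theta(fit, r), mass)
      if (sim$params$theta[r] >= h[["lower"]] &&
          sim$params$theta[r] <= h[["upper"]]) {
        theta_hits <- theta_hits + 1L
      }
      theta_tot <- theta_tot + 1L
    }
    ho <- hdi(as.vector(fit$omega), mass)
    if (sim$params$omega >= ho[["lower"]] &&
        sim$params$omega <= ho[["upper"]]) {
      omega_hits <- omega_hits + 1L
    }
  }
  n_used <- n_replicates - n_excluded
  if (n_used == 0L) stop("all replicates failed the convergence contract")
  list(theta_coverage = theta_hits / theta_tot,
       omega_coverage = omega_hits / n_used,
       n_theta = theta_tot, n_used = n_used,
       n_excluded = n_excluded, mass = mass)
}
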