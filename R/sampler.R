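#' Sampler settings for the Metropolis-within-Gibbs posterior sampler
#'
#' Defaults are sized so that, on a standard group of about 10 plates of 20
#' animals, the effective sample size of every parameter (omega, kappa and
#' each plate theta) comfortably exceeds the convergence contract of
#' `target_ess = 10000`. The plate-level theta are updated by exact
#' conjugate Gibbs draws, so almost all autocorrelation lives in the two
#' random-walk updates; the draw budget is set for those.
#'
#' @param n_chains number of independent chains (default 4).
#' @param n_warmup warmup iterations per chain, discarded; step sizes adapt
#'   only here.
#' @param n_draws kept draws per chain.
#' @param seed integer master seed; chain seeds derive from it.
#' @param step_omega,step_kappa initial random-walk scales on logit(omega)
#'   and log(kappa - offset); adapted toward 44% acceptance during warmup,
#'   then frozen.
#' @param target_ess minimum effective sample size demanded of every
#'   parameter (default 10000); a fit below it is flagged, not discarded.
#' @param rhat_max maximum allowed split-R-hat (default 1.01).
#' @return An object of class `mf_settings`.
#' @export
sampler_settings <- function(n_chains = 4L, n_warmup = 2000L,
                             n_draws = 25000L, seed = 1L,
                             step_omega = 0.5, step_kappa = 0.5,
                             target_ess = 10000, rhat_max = 1.01) {
  n_chains <- as.integer(n_chains)
  n_warmup <- as.integer(n_warmup)
  n_draws <- as.integer(n_draws)
  stopifnot(n_chains >= 1L, n_warmup >= 1L, n_draws >= 1L,
            step_omega > 0, step_kappa > 0, target_ess > 0, rhat_max >= 1)
  structure(list(n_chains = n_chains, n_warmup = n_warmup,
                 n_draws = n_draws, seed = as.integer(seed),
                 step_omega = step_omega, step_kappa = step_kappa,
                 target_ess = target_ess, rhat_max = rhat_max),
            class = "mf_settings")
}

#' Sample the posterior of one group by Metropolis-within-Gibbs
#'
#' Alternates (i) exact conjugate Gibbs draws of every plate-level theta,
#' (ii) random-walk Metropolis on logit(omega) and (iii) random-walk
#' Metropolis on log(kappa - offset), the latter two with the
#' change-of-variable Jacobians in the acceptance ratio. Step sizes adapt
#' during warmup only. Identical `settings` (including seed) and data give
#' bitwise-identical draws.
#'
#' Convergence is checked against the contract in `settings` (ESS of every
#' parameter at least `target_ess`, split-R-hat at most `rhat_max`). A
#' failing fit is returned with `converged = FALSE` and a structured warning
#' of class `mf_convergence_warning` — never silently, and never as an
#' error, so partial results stay inspectable.
#'
#' @param group an [mf_group()].
#' @param prior an [hyper_prior()].
#' @param settings an [sampler_settings()].
#' @return An object of class `mf_draws`: list with `omega`, `kappa` (draw
#'   x chain matrices), `theta` (draw x chain x plate array), `group`,
#'   `settings`, `diagnostics` (per-parameter `ess` and `rhat`,
#'   acceptance rates) and `converged`.
#' @export
sample_posterior <- function(group, prior = hyper_prior(),
                             settings = sampler_settings()) {
  stopifnot(inherits(group, "mf_group"), inherits(prior, "mf_prior"),
            inherits(settings, "mf_settings"))
  k <- group$plates$n_eu
  n <- group$plates$n_animals
  R <- length(k)

  set.seed(settings$seed)
  chain_seeds <- sample.int(2147483646L, settings$n_chains)

  # moment-style initial values, jittered per chain for overdispersed starts
  omega0 <- min(max((sum(k) + 1) / (sum(n) + 2), 0.02), 0.98)
  kappa0 <- prior$kappa_offset + prior$kappa_shape / prior$kappa_rate

  omega_d <- matrix(NA_real_, settings$n_draws, settings$n_chains)
  kappa_d <- matrix(NA_real_, settings$n_draws, settings$n_chains)
  theta_d <- array(NA_real_, c(settings$n_draws, settings$n_chains, R))
  accept <- matrix(NA_real_, settings$n_chains, 2,
                   dimnames = list(NULL, c("omega", "kappa")))

  for (ch in seq_len(settings$n_chains)) {
    set.seed(chain_seeds[ch])
    lo0 <- stats::qlogis(omega0) + stats::rnorm(1, 0, 0.5)
    lk0 <- log(kappa0 - prior$kappa_offset) + stats::rnorm(1, 0, 0.5)
    res <- mwg_chain(k, n, prior$alpha, prior$beta,
                     prior$kappa_shape, prior$kappa_rate,
                     prior$kappa_offset,
                     settings$n_warmup, settings$n_draws,
                     settings$step_omega, settings$step_kappa,
                     stats::plogis(lo0), prior$kappa_offset + exp(lk0))
    omega_d[, ch] <- res$omega
    kappa_d[, ch] <- res$kappa
    theta_d[, ch, ] <- res$theta
    accept[ch, ] <- c(res$accept_omega, res$accept_kappa)
  }

  par_names <- c("omega", "kappa", paste0("theta[", seq_len(R), "]"))
  draws_list <- c(list(omega_d, kappa_d),
                  lapply(seq_len(R), function(r) theta_d[, , r, drop = TRUE]))
  ess_v <- vapply(draws_list, function(m) ess(as.matrix(m)), numeric(1))
  rhat_v <- vapply(draws_list, function(m) split_rhat(as.matrix(m)),
                   numeric(1))
  names(ess_v) <- names(rhat_v) <- par_names

  converged <- min(ess_v) >= settings$target_ess &&
    max(rhat_v) <= settings$rhat_max
  out <- structure(
    list(omega = omega_d, kappa = kappa_d, theta = theta_d,
         group = group, prior = prior, settings = settings,
         diagnostics = list(ess = ess_v, rhat = rhat_v, accept = accept),
         converged = converged),
    class = "mf_draws"
  )
  if (!converged) {
    warning(warningCondition(
      sprintf(paste0("group %s/%s failed the convergence contract: ",
                     "min ESS %.0f (target %.0f), max split-Rhat %.4f ",
                     "(max %.3f)"),
              group$condition_id, group$generation, min(ess_v),
              settings$target_ess, max(rhat_v), settings$rhat_max),
      class = c("mf_convergence_warning", "warning", "condition")
    ))
  }
  out
}

#' @export
print.mf_draws <- function(x, ...) {
  cat("<mf_draws> ", x$group$condition_id, "/", x$group$generation, ": ",
      x$settings$n_chains, " chains x ", x$settings$n_draws, " draws, ",
      dim(x$theta)[3], " plates\n",
      "  min ESS ", round(min(x$diagnostics$ess)),
      ", max split-Rhat ", round(max(x$diagnostics$rhat), 4),
      if (x$converged) " (converged)" else " (FLAGGED)", "\n", sep = "")
  invisible(x)
}

#' Pool the plate-level theta draws of a fit into one vector
#'
#' @param draws an `mf_draws` object.
#' @param plate optional plate index; default pools all plates.
#' @return Numeric vector of theta draws pooled across chains (and plates).
#' @export
pool_theta <- function(draws, plate = NULL) {
  stopifnot(inherits(draws, "mf_draws"))
  if (is.null(plate)) as.vector(draws$theta)
  else as.vector(draws$theta[, , plate, drop = TRUE])
}
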