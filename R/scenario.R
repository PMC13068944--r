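#' Define a simulation scenario for an induction/reversal experiment
#'
#' A scenario encodes the study design the synthetic generator emulates: a
#' baseline Eu probability on the control diet, a (near-complete) induced
#' probability on the inducing diet, plate-to-plate heterogeneity through the
#' concentration `kappa_true`, and a geometric decay of the induced excess
#' after reversal. Defaults mirror the laboratory design: the RSC011 strain
#' is preferentially non-predatory (about 30% Eu) on the control diet,
#' induction is near-complete, and each generation is scored on 10 plates of
#' 20 animals.
#'
#' @param baseline_omega Eu-probability mode on the control diet, in (0,1).
#' @param induced_omega Eu-probability mode at full induction, in (0,1).
#'   Complete induction is encoded as 0.995: a Beta mode of exactly 1 lies
#'   outside the mode-concentration parameterization.
#' @param kappa_true concentration (> 2) of plate-level theta around omega.
#' @param retention per-generation geometric retention in \[0,1\] of the
#'   induced excess after reversal: reversal generation m has
#'   `omega = baseline + (induced - baseline) * retention^m`.
#' @param n_induction_generations,n_reversal_generations number of
#'   generations in each phase.
#' @param plates_per_generation,animals_per_plate experimental design; the
#'   laboratory standard is at least 10 plates of 20 animals.
#' @param induction_lag generations before `induced_omega` is reached
#'   (linear ramp; 0 = immediate induction, as observed on the inducing
#'   diets).
#' @return An object of class `mf_scenario` (a validated list).
#' @seealso [build_trajectory()], [simulate_counts()], [scenario_preset()]
#' @export
scenario_spec <- function(baseline_omega = 0.3,
                          induced_omega = 0.995,
                          kappa_true = 10,
                          retention = 0.95,
                          n_induction_generations = 5L,
                          n_reversal_generations = 5L,
                          plates_per_generation = 10L,
                          animals_per_plate = 20L,
                          induction_lag = 0L) {
  stopifnot(
    is.numeric(baseline_omega), length(baseline_omega) == 1L,
    is.numeric(induced_omega), length(induced_omega) == 1L,
    is.numeric(kappa_true), length(kappa_true) == 1L,
    is.numeric(retention), length(retention) == 1L
  )
  if (baseline_omega <= 0 || baseline_omega >= 1 ||
      induced_omega <= 0 || induced_omega >= 1) {
    stop("omega values must lie strictly inside (0, 1); encode complete ",
         "induction as e.g. 0.995, never 1.0")
  }
  if (kappa_true <= 2) stop("kappa_true must exceed 2")
  if (retention < 0 || retention > 1) stop("retention must lie in [0, 1]")
  n_ind <- as.integer(n_induction_generations)
  n_rev <- as.integer(n_reversal_generations)
  plates <- as.integer(plates_per_generation)
  animals <- as.integer(animals_per_plate)
  lag <- as.integer(induction_lag)
  if (n_ind < 1L) stop("n_induction_generations must be >= 1")
  if (n_rev < 0L) stop("n_reversal_generations must be >= 0")
  if (plates < 1L) stop("plates_per_generation must be >= 1")
  if (animals < 1L) stop("animals_per_plate must be >= 1")
  if (lag < 0L) stop("induction_lag must be >= 0")
  structure(
    list(baseline_omega = baseline_omega,
         induced_omega = induced_omega,
         kappa_true = kappa_true,
         retention = retention,
         n_induction_generations = n_ind,
         n_reversal_generations = n_rev,
         plates_per_generation = plates,
         animals_per_plate = animals,
         induction_lag = lag),
    class = "mf_scenario"
  )
}

#' Canned scenarios for the three qualitative memory outcomes
#'
#' Three presets emulate the qualitative regimes observed across inducing
#' conditions: `"fast_decay"` (short, intergenerational memory, as at a low
#' inducing dose), `"slow_decay"` (transgenerational memory, as at high
#' doses), and `"no_retention"` (immediate return to baseline, as on a diet
#' lacking the inducing metabolite). Retention values are design choices of
#' this package; the decay law is geometric (see [build_trajectory()]).
#'
#' The presets use 30 plates per generation — within the laboratory design
#' envelope (5-10 plates as the floor, up to 60 assayed per condition) —
#' because pooled-theta intervals at the 10-plate floor are too wide for
#' reliable qualitative calls near the baseline band.
#'
#' @param name one of `"fast_decay"`, `"slow_decay"`, `"no_retention"`.
#' @return An `mf_scenario`.
#' @export
scenario_preset <- function(name = c("fast_decay", "slow_decay",
                                     "no_retention")) {
  name <- match.arg(name)
  retention <- switch(name,
    fast_decay = 0.72,
    slow_decay = 0.95,
    no_retention = 0
  )
  scenario_spec(retention = retention, kappa_true = 50,
                plates_per_generation = 30L)
}

#' Ground-truth omega trajectory implied by a scenario
#'
#' Induction generations ramp linearly from `baseline_omega` to
#' `induced_omega` over `induction_lag` generations and then hold (a lag of
#' 0 reproduces the immediate, generation-1 induction observed on inducing
#' diets; a positive lag reproduces induction that builds over several
#' generations, as under methionine supplementation). Reversal generation m
#' decays geometrically:
#' `omega_m = baseline + (induced - baseline) * retention^m`.
#'
#' @param scenario an [scenario_spec()] object.
#' @return A data frame with columns `label`, `phase`, `exposure_index`,
#'   `reversal_index`, `omega_true`, `kappa_true`, ordered as the experiment
#'   runs.
#' @export
build_trajectory <- function(scenario) {
  stopifnot(inherits(scenario, "mf_scenario"))
  s <- scenario
  excess <- s$induced_omega - s$baseline_omega
  g_ind <- seq_len(s$n_induction_generations)
  omega_ind <- s$baseline_omega +
    excess * pmin(1, g_ind / (s$induction_lag + 1))
  lab_ind <- sprintf("F%d", g_ind)
  out <- data.frame(
    label = lab_ind,
    phase = "induction",
    exposure_index = g_ind,
    reversal_index = 0L,
    omega_true = omega_ind,
    stringsAsFactors = FALSE
  )
  if (s$n_reversal_generations > 0L) {
    m <- seq_len(s$n_reversal_generations)
    out <- rbind(out, data.frame(
      label = sprintf("F%dR%d", s$n_induction_generations, m),
      phase = "reversal",
      exposure_index = s$n_induction_generations,
      reversal_index = m,
      omega_true = s$baseline_omega + excess * s$retention^m,
      stringsAsFactors = FALSE
    ))
  }
  out$kappa_true <- s$kappa_true
  rownames(out) <- NULL
  out
}

# Derive one sub-seed per generation from the master seed. sample.int draws
# sequentially from the seeded stream, so the first k sub-seeds do not change
# when more generations are appended.
generation_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

#' Simulate plate-level Eu counts from a ground-truth trajectory
#'
#' The generative direction of the hierarchical model: for each generation
#' with truth (omega, kappa), each plate draws its own Eu probability
#' `theta_r ~ Beta(omega*(kappa-2)+1, (1-omega)*(kappa-2)+1)` and scores
#' `n_eu ~ Binomial(animals_per_plate, theta_r)`. The per-animal Bernoulli
#' outcomes are aggregated to the binomial plate count (the sufficient
#' statistic; the likelihood is identical).
#'
#' One integer seed reproduces the whole table bitwise; per-generation
#' sub-streams are derived from it so appending generations leaves earlier
#' generations' counts unchanged.
#'
#' @param truth data frame as returned by [build_trajectory()] (columns
#'   `label`, `omega_true`, `kappa_true`).
#' @param scenario an [scenario_spec()] (supplies plate/animal counts).
#' @param seed integer master seed.
#' @param condition_id label stored in the `condition_id` column.
#' @return A plate table: data frame with columns `condition_id`,
#'   `generation`, `replicate_id`, `n_animals`, `n_eu`.
#' @export
simulate_counts <- function(truth, scenario, seed, condition_id = "sim") {
  stopifnot(is.data.frame(truth), nrow(truth) >= 1L,
            all(c("label", "omega_true", "kappa_true") %in% names(truth)),
            inherits(scenario, "mf_scenario"))
  if (any(truth$kappa_true <= 2)) {
    stop("kappa_true must exceed 2: the Beta shapes ",
         "omega*(kappa-2)+1, (1-omega)*(kappa-2)+1 parameterize a mode ",
         "only for kappa > 2")
  }
  if (any(truth$omega_true <= 0 | truth$omega_true >= 1)) {
    stop("omega_true must lie strictly inside (0, 1)")
  }
  R <- scenario$plates_per_generation
  n <- scenario$animals_per_plate
  seeds <- generation_seeds(seed, nrow(truth))
  rows <- lapply(seq_len(nrow(truth)), function(g) {
    set.seed(seeds[g])
    sh <- beta_shapes_from_mode(truth$omega_true[g], truth$kappa_true[g])
    theta <- stats::rbeta(R, sh[["a"]], sh[["b"]])
    k <- stats::rbinom(R, size = n, prob = theta)
    data.frame(
      condition_id = condition_id,
      generation = truth$label[g],
      replicate_id = sprintf("%s_p%02d", truth$label[g], seq_len(R)),
      n_animals = n,
      n_eu = k,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw one dataset from the prior predictive of the hierarchical model
#'
#' Draws `omega ~ Beta(alpha, beta)`, `kappa = offset + Gamma(shape, rate)`,
#' per-plate `theta_r` from the mode-concentration Beta and counts
#' binomially, returning the latent truth alongside the plate table. This is
#' the generator used by simulation-based calibration: data simulated from
#' the model's own prior must yield credible intervals with nominal
#' coverage.
#'
#' @param prior an [hyper_prior()] object.
#' @param plates,animals design of the simulated group.
#' @param seed integer seed.
#' @param condition_id,generation labels stored in the plate table.
#' @return A list with elements `params` (list `omega`, `kappa`, `theta`)
#'   and `table` (plate table as in [simulate_counts()]).
#' @export
simulate_prior_predictive <- function(prior, plates = 10L, animals = 20L,
                                      seed, condition_id = "prior_pred",
                                      generation = "F1") {
  stopifnot(inherits(prior, "mf_prior"), plates >= 1L, animals >= 1L)
  set.seed(as.integer(seed))
  omega <- stats::rbeta(1, prior$alpha, prior$beta)
  kappa <- prior$kappa_offset +
    stats::rgamma(1, shape = prior$kappa_shape, rate = prior$kappa_rate)
  sh <- beta_shapes_from_mode(omega, kappa)
  theta <- stats::rbeta(plates, sh[["a"]], sh[["b"]])
  k <- stats::rbinom(plates, size = animals, prob = theta)
  list(
    params = list(omega = omega, kappa = kappa, theta = theta),
    table = data.frame(
      condition_id = condition_id,
      generation = generation,
      replicate_id = sprintf("p%02d", seq_len(plates)),
      n_animals = as.integer(animals),
      n_eu = k,
      stringsAsFactors = FALSE
    )
  )
}
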