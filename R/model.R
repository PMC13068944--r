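#' Hyperpriors of the hierarchical mouth-form model
#'
#' The model places `omega ~ Beta(alpha, beta)` on the generation-level mode
#' and a Gamma prior on the concentration. The literal concentration prior
#' `kappa ~ Gamma(3, 1)` admits `kappa < 2`, where the mode
#' parameterization's Beta shapes can become non-positive; the default here
#' is the shifted form `kappa = kappa_offset + Gamma(kappa_shape,
#' kappa_rate)` with `kappa_offset = 2`, which guarantees valid shapes while
#' keeping the Gamma(3, 1) law (shape 3, *rate* 1, mean 3). Set
#' `kappa_offset = 0` for the unshifted prior.
#'
#' `alpha = beta = 1` (uniform mode prior) is the default; it is
#' uninformative and preserves the model's symmetry under relabelling the
#' two morphs.
#'
#' @param alpha,beta Beta hyperprior on omega; both > 0.
#' @param kappa_shape,kappa_rate Gamma prior on `kappa - kappa_offset`;
#'   both > 0.
#' @param kappa_offset lower bound of the kappa support; >= 0.
#' @return An object of class `mf_prior`.
#' @export
hyper_prior <- function(alpha = 1, beta = 1, kappa_shape = 3,
                        kappa_rate = 1, kappa_offset = 2) {
  vals <- c(alpha = alpha, beta = beta, kappa_shape = kappa_shape,
            kappa_rate = kappa_rate)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("alpha, beta, kappa_shape and kappa_rate must be positive finite")
  }
  if (!is.finite(kappa_offset) || kappa_offset < 0) {
    stop("kappa_offset must be >= 0")
  }
  structure(list(alpha = alpha, beta = beta, kappa_shape = kappa_shape,
                 kappa_rate = kappa_rate, kappa_offset = kappa_offset),
            class = "mf_prior")
}

#' Mode-concentration parameterization of the Beta distribution
#'
#' Maps the generation-level mode omega and concentration kappa to the Beta
#' shapes `a = omega*(kappa-2) + 1`, `b = (1-omega)*(kappa-2) + 1`. Then
#' `a + b = kappa` and, for `kappa > 2`, the mode `(a-1)/(a+b-2)` equals
#' omega. At `kappa = 2` the distribution is uniform regardless of omega.
#'
#' @param omega mode, strictly in (0, 1).
#' @param kappa concentration; any value yielding positive shapes is
#'   accepted (in particular all `kappa >= 2`).
#' @return Named numeric vector `c(a = , b = )` (vectorized over inputs).
#' @export
beta_shapes_from_mode <- function(omega, kappa) {
  if (any(!is.finite(omega)) || any(omega <= 0) || any(omega >= 1)) {
    stop("omega must lie strictly inside (0, 1)")
  }
  a <- omega * (kappa - 2) + 1
  b <- (1 - omega) * (kappa - 2) + 1
  if (any(!is.finite(a)) || any(a <= 0) || any(b <= 0)) {
    stop("kappa = ", paste(signif(kappa, 4), collapse = ", "),
         " yields non-positive Beta shapes at omega = ",
         paste(signif(omega, 4), collapse = ", "))
  }
  if (length(a) == 1L) c(a = a, b = b) else cbind(a = a, b = b)
}

#' Bundle the plates of one (condition, generation) group
#'
#' The hierarchical model is fitted independently to each group: the
#' hyperparameters omega and kappa link the biological replicates (plates)
#' of a given generation under a given experimental condition.
#'
#' @param condition_id condition label.
#' @param generation generation label (must parse, e.g. `"F5R2"`).
#' @param n_eu integer vector, Eu animals per plate.
#' @param n_animals integer vector (or scalar), animals scored per plate.
#' @param replicate_id optional plate labels.
#' @return An object of class `mf_group` with elements `condition_id`,
#'   `generation`, `plates` (data frame `replicate_id`, `n_animals`,
#'   `n_eu`).
#' @export
mf_group <- function(condition_id, generation, n_eu, n_animals,
                     replicate_id = NULL) {
  parse_generation(generation)  # validates the label grammar
  n_eu <- as.integer(n_eu)
  n_animals <- as.integer(rep_len(n_animals, length(n_eu)))
  if (length(n_eu) < 1L) stop("a group needs at least one plate")
  if (any(n_animals < 1L)) stop("n_animals must be >= 1")
  if (any(n_eu < 0L) || any(n_eu > n_animals)) {
    stop("counts must satisfy 0 <= n_eu <= n_animals")
  }
  if (length(n_eu) < 5L) {
    warning("group ", condition_id, "/", generation, " has only ",
            length(n_eu), " plates; the design standard is 5-10 or more",
            call. = FALSE)
  }
  if (is.null(replicate_id)) {
    replicate_id <- sprintf("p%02d", seq_along(n_eu))
  }
  structure(
    list(condition_id = condition_id,
         generation = generation,
         plates = data.frame(replicate_id = as.character(replicate_id),
                             n_animals = n_animals, n_eu = n_eu,
                             stringsAsFactors = FALSE)),
    class = "mf_group"
  )
}

#' @export
print.mf_group <- function(x, ...) {
  cat("<mf_group> ", x$condition_id, " / ", x$generation, ": ",
      nrow(x$plates), " plates, ",
      sum(x$plates$n_eu), "/", sum(x$plates$n_animals), " Eu\n", sep = "")
  invisible(x)
}

check_params <- function(omega, kappa, theta, prior) {
  if (!is.finite(omega) || omega <= 0 || omega >= 1) {
    stop("omega outside support (0, 1): ", omega)
  }
  if (!is.finite(kappa) || kappa <= prior$kappa_offset) {
    stop("kappa outside support (kappa_offset, Inf): ", kappa)
  }
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta >= 1)) {
    stop("theta outside support (0, 1)")
  }
  invisible(TRUE)
}

#' Log joint posterior density (unnormalized) of one group
#'
#' Sums, with all normalizing constants retained: the binomial
#' log-likelihood of each plate's count given its theta, the
#' mode-concentration Beta log-density of each theta given (omega, kappa),
#' the Beta(alpha, beta) log-density of omega, and the Gamma log-density of
#' `kappa - kappa_offset`. Only the binomial coefficient (a function of the
#' data alone) would be a droppable constant; it is kept so the value is a
#' genuine log joint density.
#'
#' Arguments outside the parameter support raise an error; the sampler uses
#' the distinct entry point [log_posterior_or_inf()], which returns `-Inf`
#' instead.
#'
#' @param omega,kappa,theta model parameters; `theta` has one entry per
#'   plate of `group`.
#' @param group an [mf_group()].
#' @param prior an [hyper_prior()].
#' @return A finite scalar for interior parameter values.
#' @export
log_posterior <- function(omega, kappa, theta, group, prior) {
  stopifnot(inherits(group, "mf_group"), inherits(prior, "mf_prior"))
  if (length(theta) != nrow(group$plates)) {
    stop("theta must have one entry per plate")
  }
  check_params(omega, kappa, theta, prior)
  sh <- beta_shapes_from_mode(omega, kappa)
  sum(stats::dbinom(group$plates$n_eu, group$plates$n_animals, theta,
                    log = TRUE)) +
    sum(stats::dbeta(theta, sh[["a"]], sh[["b"]], log = TRUE)) +
    stats::dbeta(omega, prior$alpha, prior$beta, log = TRUE) +
    stats::dgamma(kappa - prior$kappa_offset, shape = prior$kappa_shape,
                  rate = prior$kappa_rate, log = TRUE)
}

#' Sampler-facing log posterior: `-Inf` outside the support
#'
#' Identical to [log_posterior()] on the interior of the parameter space but
#' returns `-Inf` (never an error) outside it, so Metropolis proposals that
#' step out of the support are simply rejected.
#'
#' @inheritParams log_posterior
#' @return A scalar, possibly `-Inf`.
#' @export
log_posterior_or_inf <- function(omega, kappa, theta, group, prior) {
  ok <- is.finite(omega) && omega > 0 && omega < 1 &&
    is.finite(kappa) && kappa > prior$kappa_offset &&
    all(is.finite(theta)) && all(theta > 0) && all(theta < 1) &&
    (omega * (kappa - 2) + 1) > 0 && ((1 - omega) * (kappa - 2) + 1) > 0
  if (!ok) return(-Inf)
  log_posterior(omega, kappa, theta, group, prior)
}

#' Exact conjugate Gibbs draw of the plate-level theta vector
#'
#' Given (omega, kappa), each plate's theta is conditionally independent
#' with a conjugate Beta posterior: `theta_r ~ Beta(a + k_r, b + n_r - k_r)`
#' where `(a, b)` are the mode-concentration shapes, `k_r` the plate's Eu
#' count and `n_r` its animals scored.
#'
#' @inheritParams log_posterior
#' @return Numeric vector of fresh theta draws, one per plate.
#' @export
gibbs_update_theta <- function(group, omega, kappa) {
  stopifnot(inherits(group, "mf_group"))
  sh <- beta_shapes_from_mode(omega, kappa)
  k <- group$plates$n_eu
  n <- group$plates$n_animals
  stats::rbeta(length(k), sh[["a"]] + k, sh[["b"]] + n - k)
}
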