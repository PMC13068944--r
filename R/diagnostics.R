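#' Highest-density interval of a sample
#'
#' Sample-based HDI: over the sorted samples, the narrowest window
#' containing `w = ceiling(mass * N)` of the `N` draws; ties are broken by
#' the lowest start index. This is the error bar plotted for each group
#' (the 95% HDI of the pooled plate-level theta draws).
#'
#' @param samples numeric vector; at least 100 values when `mass < 1`.
#' @param mass interval mass in (0, 1]; `mass = 1` returns the sample range.
#' @return Numeric vector `c(lower = , upper = )` with attribute `mass`.
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("samples must not contain NA")
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass > 1) {
    stop("mass must lie in (0, 1]")
  }
  N <- length(samples)
  if (mass == 1) {
    if (N < 1L) stop("too few samples")
    out <- c(lower = min(samples), upper = max(samples))
    attr(out, "mass") <- mass
    return(out)
  }
  if (N < 100L) {
    stop("too few samples for an HDI at mass < 1 (need >= 100, got ", N, ")")
  }
  w <- ceiling(mass * N)
  s <- sort(samples)
  if (w >= N) {
    out <- c(lower = s[1L], upper = s[N])
  } else {
    widths <- s[w:N] - s[1:(N - w + 1L)]
    # lowest start index among (numerically) tied minimal widths
    tol <- 1e-8 * (s[N] - s[1L])
    i <- which(widths <= min(widths) + tol)[1L]
    out <- c(lower = s[i], upper = s[i + w - 1L])
  }
  attr(out, "mass") <- mass
  out
}

# Biased (divide-by-n) autocovariance at lags 0..n-1, via FFT.
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  L <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, L - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / L
  ac[seq_len(n)] / n
}

as_chain_matrix <- function(chain_draws) {
  if (is.list(chain_draws)) {
    lens <- lengths(chain_draws)
    if (length(unique(lens)) != 1L) stop("chains must have equal lengths")
    chain_draws <- do.call(cbind, chain_draws)
  }
  as.matrix(chain_draws)
}

# Split each column (chain) in half; the middle draw of an odd-length chain
# is dropped. Returns a matrix with 2x the chains and floor(n/2) rows.
split_chains <- function(mat) {
  n <- nrow(mat)
  h <- n %/% 2L
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[seq.int(n - h + 1L, n), , drop = FALSE])
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based ESS on rank-normalized split chains, with Geyer's
#' initial positive-sequence truncation (and monotone smoothing) of the
#' paired autocorrelations. This is the "bulk" ESS commonly used to verify
#' the convergence contract ESS >= 10000.
#'
#' @param chain_draws an iterations x chains matrix, a list of equal-length
#'   numeric vectors, or a single numeric vector (one chain; needs >= 1000
#'   draws).
#' @return A positive scalar; 0 (with a warning) for a degenerate constant
#'   chain.
#' @export
ess <- function(chain_draws) {
  mat <- as_chain_matrix(chain_draws)
  if (ncol(mat) < 2L && nrow(mat) < 1000L) {
    stop("need >= 2 chains, or a single chain of >= 1000 draws")
  }
  if (nrow(mat) < 8L) stop("chains too short for an ESS estimate")
  if (isTRUE(all(mat == mat[1L]))) {
    warning("constant chain: ESS is undefined, reporting 0", call. = FALSE)
    return(0)
  }
  z <- split_chains(mat)
  # rank-normalize jointly across all split chains
  r <- rank(z, ties.method = "average")
  z[] <- stats::qnorm((r - 3 / 8) / (length(z) + 1 / 4))

  n <- nrow(z)
  m <- ncol(z)
  acov <- apply(z, 2L, autocov_fft)
  chain_mean <- colMeans(z)
  mean_var <- mean(acov[1L, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n +
    (if (m > 1L) stats::var(chain_mean) else 0)
  if (var_plus == 0) {
    warning("zero variance across split chains: reporting ESS 0",
            call. = FALSE)
    return(0)
  }

  rho <- rep(0, n)
  rho[1L] <- 1
  rho_even <- 1
  rho_odd <- 1 - (mean_var - mean(acov[2L, ])) / var_plus
  rho[2L] <- rho_odd
  t <- 0L
  while (t < n - 4L && (rho_even + rho_odd) > 0) {
    t <- t + 2L
    rho_even <- 1 - (mean_var - mean(acov[t + 1L, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(acov[t + 2L, ])) / var_plus
    if (rho_even + rho_odd >= 0) {
      rho[t + 1L] <- rho_even
      rho[t + 2L] <- rho_odd
    }
  }
  max_t <- t
  if (rho_even > 0) rho[max_t + 1L] <- rho_even
  # enforce monotone decrease of the paired sums
  t <- 0L
  while (t <= max_t - 4L) {
    t <- t + 2L
    if (rho[t + 1L] + rho[t + 2L] > rho[t - 1L] + rho[t]) {
      rho[t + 1L] <- (rho[t - 1L] + rho[t]) / 2
      rho[t + 2L] <- rho[t + 1L]
    }
  }
  S <- m * n
  tau <- -1 + 2 * sum(rho[seq_len(max_t)]) + rho[max_t + 1L]
  tau <- max(tau, 1 / log10(S))
  S / tau
}

#' Split-chain potential scale reduction factor (split-R-hat)
#'
#' Each chain is split in half and the classical potential scale reduction
#' factor `sqrt(((n-1)/n * W + B/n) / W)` is computed over the split
#' chains, so a single slowly-drifting chain is also detected. Values near
#' 1 (at most about 1.01) indicate convergence.
#'
#' @inheritParams ess
#' @return A scalar >= 1 up to floating-point tolerance for stationary
#'   chains.
#' @export
split_rhat <- function(chain_draws) {
  mat <- as_chain_matrix(chain_draws)
  if (nrow(mat) < 4L) stop("chains must have length >= 4")
  z <- split_chains(mat)
  n <- nrow(z)
  W <- mean(apply(z, 2L, stats::var))
  B <- n * stats::var(colMeans(z))
  if (W == 0) {
    warning("zero within-chain variance: split-Rhat is undefined",
            call. = FALSE)
    return(NA_real_)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize one fitted group: pooled mean, HDI and diagnostics
#'
#' Pools the plate-level theta draws of all plates and chains into one
#' vector — the group-level distribution of a replicate's Eu probability —
#' and reports its mean and HDI: one plotted point and one error bar per
#' group. Convergence diagnostics are the minimum ESS and maximum
#' split-R-hat over omega, kappa and every plate theta. Set
#' `per_plate = TRUE` for the per-replicate alternative (one row per
#' plate).
#'
#' @param draws an `mf_draws` object from [sample_posterior()].
#' @param mass HDI mass (default 0.95).
#' @param per_plate summarize each plate separately instead of pooling.
#' @return A data frame with columns `condition_id`, `generation`,
#'   `mean_theta`, `hdi_lower`, `hdi_upper`, `ess_min`, `rhat_max`,
#'   `n_plates` (plus `replicate_id` when `per_plate = TRUE`).
#' @export
summarize_group <- function(draws, mass = 0.95, per_plate = FALSE) {
  stopifnot(inherits(draws, "mf_draws"))
  R <- dim(draws$theta)[3]
  ess_min <- min(draws$diagnostics$ess)
  rhat_max <- max(draws$diagnostics$rhat)
  one <- function(v, rid = NULL) {
    h <- hdi(v, mass)
    m <- mean(v)
    if (m < h[["lower"]] || m > h[["upper"]]) {
      warning("pooled mean lies outside the HDI (multimodal pooled draws?)",
              call. = FALSE)
    }
    out <- data.frame(condition_id = draws$group$condition_id,
                      generation = draws$group$generation,
                      mean_theta = m, hdi_lower = h[["lower"]],
                      hdi_upper = h[["upper"]], ess_min = ess_min,
                      rhat_max = rhat_max, n_plates = R,
                      stringsAsFactors = FALSE)
    if (!is.null(rid)) {
      out <- cbind(out[, 1:2], replicate_id = rid, out[, -(1:2)])
    }
    out
  }
  if (!per_plate) return(one(pool_theta(draws)))
  out <- do.call(rbind, lapply(seq_len(R), function(r) {
    one(pool_theta(draws, r), draws$group$plates$replicate_id[r])
  }))
  rownames(out) <- NULL
  out
}
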