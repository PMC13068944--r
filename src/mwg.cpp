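#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs for one chain of the hierarchical beta-Bernoulli
// model: conjugate Gibbs draws for the plate-level theta, random-walk
// Metropolis on logit(omega) and on log(kappa - offset), with the change-of
// -variable Jacobians folded into the acceptance ratio. Step sizes adapt by
// Robbins-Monro toward a 0.44 acceptance probability during warmup only and
// are frozen afterwards, preserving detailed balance for the kept draws.
// Uses R's RNG throughout, so set.seed() on the R side makes a chain
// bitwise reproducible.

static inline double log_theta_terms(const NumericVector& theta,
                                     double a, double b) {
  double s = 0.0;
  for (int r = 0; r < theta.size(); ++r)
    s += R::dbeta(theta[r], a, b, 1);
  return s;
}

// [[Rcpp::export]]
List mwg_chain(IntegerVector k, IntegerVector n,
               double alpha, double beta,
               double kappa_shape, double kappa_rate, double kappa_offset,
               int n_warmup, int n_draws,
               double step_omega, double step_kappa,
               double omega_init, double kappa_init) {
  const int R_plates = k.size();
  const int n_iter = n_warmup + n_draws;
  const double target_acc = 0.44;
  const double eps = 1e-12;

  NumericVector omega_out(n_draws), kappa_out(n_draws);
  NumericMatrix theta_out(n_draws, R_plates);

  double lo = std::log(omega_init / (1.0 - omega_init));
  double lk = std::log(kappa_init - kappa_offset);
  double omega = omega_init, kappa = kappa_init;
  NumericVector theta(R_plates);

  double acc_o = 0.0, acc_k = 0.0;  // post-warmup acceptance counters

  for (int it = 0; it < n_iter; ++it) {
    // --- theta | omega, kappa, data: exact conjugate draw ---
    double a = omega * (kappa - 2.0) + 1.0;
    double b = (1.0 - omega) * (kappa - 2.0) + 1.0;
    for (int r = 0; r < R_plates; ++r) {
      double t = R::rbeta(a + k[r], b + n[r] - k[r]);
      if (t < eps) t = eps;
      if (t > 1.0 - eps) t = 1.0 - eps;
      theta[r] = t;
    }

    // --- omega | theta, kappa: RW Metropolis on logit scale ---
    // target in lo: sum_r log Beta(theta_r; a(omega), b(omega))
    //   + log Beta(omega; alpha, beta) + log omega + log(1 - omega)
    {
      double cur = log_theta_terms(theta, a, b) +
        R::dbeta(omega, alpha, beta, 1) +
        std::log(omega) + std::log(1.0 - omega);
      double lo_p = lo + step_omega * R::norm_rand();
      double omega_p = 1.0 / (1.0 + std::exp(-lo_p));
      double lratio = -INFINITY;
      if (omega_p > eps && omega_p < 1.0 - eps) {
        double a_p = omega_p * (kappa - 2.0) + 1.0;
        double b_p = (1.0 - omega_p) * (kappa - 2.0) + 1.0;
        if (a_p > 0.0 && b_p > 0.0) {
          double prop = log_theta_terms(theta, a_p, b_p) +
            R::dbeta(omega_p, alpha, beta, 1) +
            std::log(omega_p) + std::log(1.0 - omega_p);
          lratio = prop - cur;
        }
      }
      double acc_prob = (lratio >= 0.0) ? 1.0 : std::exp(lratio);
      if (R::unif_rand() < acc_prob) {
        lo = lo_p; omega = 1.0 / (1.0 + std::exp(-lo));
        a = omega * (kappa - 2.0) + 1.0;
        b = (1.0 - omega) * (kappa - 2.0) + 1.0;
      }
      if (it < n_warmup) {
        double gamma = std::pow(it + 1.0, -0.6);
        step_omega *= std::exp(gamma * (acc_prob - target_acc));
      }
      if (it >= n_warmup) acc_o += acc_prob;
    }

    // --- kappa | theta, omega: RW Metropolis on log(kappa - offset) ---
    {
      double cur = log_theta_terms(theta, a, b) +
        R::dgamma(kappa - kappa_offset, kappa_shape, 1.0 / kappa_rate, 1) +
        lk;  // Jacobian log(kappa - offset)
      double lk_p = lk + step_kappa * R::norm_rand();
      double kappa_p = kappa_offset + std::exp(lk_p);
      double lratio = -INFINITY;
      double a_p = omega * (kappa_p - 2.0) + 1.0;
      double b_p = (1.0 - omega) * (kappa_p - 2.0) + 1.0;
      if (std::isfinite(kappa_p) && a_p > 0.0 && b_p > 0.0) {
        double prop = log_theta_terms(theta, a_p, b_p) +
          R::dgamma(kappa_p - kappa_offset, kappa_shape, 1.0 / kappa_rate,
                    1) + lk_p;
        lratio = prop - cur;
      }
      double acc_prob = (lratio >= 0.0) ? 1.0 : std::exp(lratio);
      if (R::unif_rand() < acc_prob) {
        lk = lk_p; kappa = kappa_p;
      }
      if (it < n_warmup) {
        double gamma = std::pow(it + 1.0, -0.6);
        step_kappa *= std::exp(gamma * (acc_prob - target_acc));
      }
      if (it >= n_warmup) acc_k += acc_prob;
    }

    if (it >= n_warmup) {
      int d = it - n_warmup;
      omega_out[d] = omega;
      kappa_out[d] = kappa;
      for (int r = 0; r < R_plates; ++r) theta_out(d, r) = theta[r];
    }
  }

  return List::create(
    _["omega"] = omega_out,
    _["kappa"] = kappa_out,
    _["theta"] = theta_out,
    _["accept_omega"] = acc_o / n_draws,
    _["accept_kappa"] = acc_k / n_draws,
    _["step_omega"] = step_omega,
    _["step_kappa"] = step_kappa
  );
}
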