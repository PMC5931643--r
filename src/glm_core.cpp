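// Core numerics for the softplus-kappa Poisson GLM: likelihood, damped
// Newton MLE, observed Fisher information, and the bin-by-bin network
// simulators (Poisson and LIF).  Hot loops live here; R-level reference
// implementations of the same quantities exist for cross-checking.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// lambda(eta) = log(1 + exp(kappa * eta)) / kappa, overflow-safe.
static inline double softplus_k(double eta, double kappa) {
  double z = kappa * eta;
  if (z > 30.0) return eta + std::log1p(std::exp(-z)) / kappa;
  return std::log1p(std::exp(z)) / kappa;
}

// log(lambda(eta)); for very negative kappa*eta, lambda ~ exp(z)/kappa.
static inline double log_softplus_k(double eta, double kappa) {
  double z = kappa * eta;
  if (z < -30.0) return z - std::log(kappa);
  return std::log(softplus_k(eta, kappa));
}

static inline double sigmoid(double z) {
  if (z >= 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// ratio lambda'(eta)/lambda(eta), stable as kappa*eta -> -Inf (limit kappa).
static inline double dlog_lambda(double eta, double kappa) {
  double z = kappa * eta;
  if (z < -30.0) return kappa;       // sigma(z)/softplus(z) -> kappa
  double sp = softplus_k(eta, kappa);
  return sigmoid(z) / sp;
}

static double loglik_eta(const arma::vec& y, const arma::vec& eta, double kappa) {
  double ll = 0.0;
  for (arma::uword t = 0; t < y.n_elem; ++t) {
    double lam = softplus_k(eta[t], kappa);
    ll += y[t] * log_softplus_k(eta[t], kappa) - lam;
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_glm_loglik(const arma::vec& y, const arma::mat& R,
                      const arma::vec& theta, double kappa) {
  arma::vec eta = R * theta;
  return loglik_eta(y, eta, kappa);
}

// Per-bin weights of the observed Fisher information (closed form):
//   w_t = y * (lambda'/lambda)^2 + kappa * (1 - y/lambda) * s * (1 - s)
// with s = sigmoid(kappa * eta); J = R' diag(w) R.
static arma::vec fisher_weights(const arma::vec& y, const arma::vec& eta, double kappa) {
  arma::vec w(y.n_elem);
  for (arma::uword t = 0; t < y.n_elem; ++t) {
    double z = kappa * eta[t];
    double s = sigmoid(z);
    double lam = softplus_k(eta[t], kappa);
    double r = dlog_lambda(eta[t], kappa);
    w[t] = y[t] * r * r + kappa * (1.0 - y[t] / lam) * s * (1.0 - s);
  }
  return w;
}

// [[Rcpp::export]]
arma::mat cpp_observed_fisher(const arma::vec& y, const arma::mat& R,
                              const arma::vec& theta, double kappa) {
  arma::vec eta = R * theta;
  arma::vec w = fisher_weights(y, eta, kappa);
  return R.t() * (R.each_col() % w);
}

// Damped Newton ascent on the concave log-likelihood.  Convergence when the
// gradient max-norm drops below gtol or the relative log-likelihood change
// drops below lltol; at most maxit iterations.
// [[Rcpp::export]]
List cpp_glm_newton(const arma::vec& y, const arma::mat& R, double kappa,
                    const arma::vec& init, int maxit = 500,
                    double gtol = 1e-6, double lltol = 1e-9) {
  arma::vec theta = init;
  arma::vec eta = R * theta;
  double ll = loglik_eta(y, eta, kappa);
  bool converged = false;
  int it = 0;
  arma::vec gw(y.n_elem), w(y.n_elem);
  for (it = 0; it < maxit; ++it) {
    // single pass: gradient weight y*lambda'/lambda - lambda' and the
    // Fisher weight share sigmoid/softplus evaluations
    for (arma::uword t = 0; t < y.n_elem; ++t) {
      double z = kappa * eta[t];
      double s = sigmoid(z);
      double lam, r;
      if (z < -30.0) { lam = std::exp(z) / kappa; r = kappa; }
      else { lam = std::log1p(std::exp(z > 30.0 ? 0.0 : z)) / kappa;
             if (z > 30.0) lam = eta[t] + std::log1p(std::exp(-z)) / kappa;
             r = s / lam; }
      gw[t] = y[t] * r - s;
      double wt = y[t] * r * r + kappa * (1.0 - y[t] / lam) * s * (1.0 - s);
      // Guard: near the optimum w >= 0 by concavity; clamp stray
      // negatives from finite-sample curvature so the step stays an
      // ascent direction.
      w[t] = wt > 0.0 ? wt : 0.0;
    }
    arma::vec g = R.t() * gw;
    if (arma::abs(g).max() < gtol) { converged = true; break; }

    arma::mat J = R.t() * (R.each_col() % w);
    arma::vec step;
    bool ok = arma::solve(step, J, g, arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok) {
      J.diag() += 1e-8 * (1.0 + arma::trace(J) / J.n_rows);
      ok = arma::solve(step, J, g);
      if (!ok) break;
    }
    // backtracking line search on the log-likelihood
    double alpha = 1.0;
    double ll_new = ll;
    arma::vec theta_new = theta;
    bool improved = false;
    for (int h = 0; h < 40; ++h) {
      theta_new = theta + alpha * step;
      arma::vec eta_new = R * theta_new;
      ll_new = loglik_eta(y, eta_new, kappa);
      if (std::isfinite(ll_new) && ll_new >= ll) { improved = true; eta = eta_new; break; }
      alpha *= 0.5;
    }
    if (!improved) break;
    double rel = std::fabs(ll_new - ll) / (std::fabs(ll) + 1e-12);
    theta = theta_new;
    ll = ll_new;
    if (rel < lltol) { converged = true; ++it; break; }
  }
  arma::mat J = cpp_observed_fisher(y, R, theta, kappa);
  return List::create(_["theta"] = theta, _["loglik"] = ll,
                      _["converged"] = converged, _["iterations"] = it,
                      _["fisher"] = J);
}

// L1-penalized path for the softplus-kappa Poisson GLM: proximal
// gradient (ISTA) with backtracking, warm-started along the descending
// penalty grid.  The bias (last column) is unpenalized.
// [[Rcpp::export]]
arma::mat cpp_lasso_path(const arma::vec& y, const arma::mat& R,
                         double kappa, const arma::vec& l1Grid,
                         const arma::vec& init, int maxit = 400,
                         double movedTol = 1e-7) {
  int p = R.n_cols;
  arma::vec theta = init;
  arma::mat coefs(p, l1Grid.n_elem, arma::fill::zeros);
  double stepSize = 1.0 / std::max(1.0, arma::accu(arma::square(R)) / y.n_elem);

  auto nll = [&](const arma::vec& th) {
    arma::vec eta = R * th;
    return -loglik_eta(y, eta, kappa);
  };
  auto grad = [&](const arma::vec& th) {
    arma::vec eta = R * th;
    arma::vec gw(y.n_elem);
    for (arma::uword t = 0; t < y.n_elem; ++t) {
      double s = sigmoid(kappa * eta[t]);
      double r = dlog_lambda(eta[t], kappa);
      gw[t] = -(y[t] * r - s);   // gradient of the NEGATIVE log-likelihood
    }
    return arma::vec(R.t() * gw);
  };
  auto prox = [&](const arma::vec& th, double l1, double t) {
    arma::vec out = arma::sign(th) % arma::max(arma::abs(th) - t * l1,
                                               arma::zeros(th.n_elem));
    out[p - 1] = th[p - 1];      // bias unpenalized
    return out;
  };

  for (arma::uword gi = 0; gi < l1Grid.n_elem; ++gi) {
    double l1 = l1Grid[gi];
    double t = stepSize;
    double f = nll(theta);
    for (int it = 0; it < maxit; ++it) {
      arma::vec g = grad(theta);
      bool accepted = false;
      arma::vec thNew;
      double fNew = f;
      for (int h = 0; h < 40; ++h) {
        thNew = prox(theta - t * g, l1, t);
        arma::vec d = thNew - theta;
        fNew = nll(thNew);
        if (std::isfinite(fNew) &&
            fNew <= f + arma::dot(g, d) + arma::dot(d, d) / (2 * t) + 1e-12) {
          accepted = true;
          break;
        }
        t *= 0.5;
      }
      if (!accepted) break;
      double moved = arma::abs(thNew - theta).max();
      theta = thNew;
      f = fNew;
      t *= 1.5;
      if (moved < movedTol) break;
    }
    coefs.col(gi) = theta;
  }
  return coefs;
}

// Forward simulation of the fitted/ground-truth Poisson network.
// stim: n_bins x n_s indicator matrix (already holds the presented
// sequence); u: n_bins x n_c uniforms inverted through qpois so that two
// calls with common u are coupled (common random numbers).
// Boxcar history sums run over bins [t - Dl, t - Du]; early bins use the
// partially available history.
// [[Rcpp::export]]
List cpp_simulate_poisson(const arma::mat& W, const arma::mat& H,
                          const arma::vec& b, double kappa,
                          const arma::mat& stim, int Dl, int Du,
                          const arma::mat& u) {
  int m = stim.n_rows;
  int nc = b.n_elem;
  int ns = stim.n_cols;
  arma::imat counts(m, nc, arma::fill::zeros);
  arma::vec rate_sum(nc, arma::fill::zeros);
  arma::vec xhat(nc), ihat(ns);
  for (int t = 0; t < m; ++t) {
    xhat.zeros(); ihat.zeros();
    int lo = t - Dl, hi = t - Du;
    for (int tt = std::max(lo, 0); tt <= hi; ++tt) {
      if (tt >= m) break;
      for (int j = 0; j < nc; ++j) xhat[j] += counts(tt, j);
      for (int s = 0; s < ns; ++s) ihat[s] += stim(tt, s);
    }
    for (int c = 0; c < nc; ++c) {
      double eta = b[c];
      for (int j = 0; j < nc; ++j) if (W(j, c) != 0.0) eta += W(j, c) * xhat[j];
      for (int s = 0; s < ns; ++s) if (H(s, c) != 0.0) eta += H(s, c) * ihat[s];
      double lam = softplus_k(eta, kappa);
      rate_sum[c] += lam;
      counts(t, c) = (int) R::qpois(u(t, c), lam, 1, 0);
    }
  }
  return List::create(_["counts"] = counts, _["rate_mean"] = rate_sum / m);
}

// Leaky integrate-and-fire network, Euler-discretized with one step per
// bin: v(t+1) = v(t) + dt * (-v(t) + b(t) + synaptic input), threshold 1,
// reset 0.  Synaptic kernel h(k) = a^2 exp(-a (k - tD)) (k - tD) for
// k >= tD, truncated at kernel_len bins.
// [[Rcpp::export]]
arma::imat cpp_simulate_lif(const arma::mat& W, const arma::mat& H,
                            const arma::mat& bcur, const arma::mat& stim,
                            double a, int tD, int kernel_len, double dt = 1.0) {
  int m = stim.n_rows;
  int nc = W.n_rows;
  int ns = stim.n_cols;
  arma::vec h(kernel_len, arma::fill::zeros);
  for (int k = 0; k < kernel_len; ++k) {
    double x = k - tD;
    if (x >= 0) h[k] = a * a * std::exp(-a * x) * x;
  }
  arma::mat input(m, nc, arma::fill::zeros);
  arma::imat spikes(m, nc, arma::fill::zeros);
  arma::vec v(nc, arma::fill::zeros);
  for (int t = 0; t < m; ++t) {
    // stimulus drive scattered forward through the kernel
    for (int s = 0; s < ns; ++s) {
      if (stim(t, s) != 0.0) {
        for (int k = 0; k < kernel_len && t + k < m; ++k) {
          if (h[k] == 0.0) continue;
          for (int c = 0; c < nc; ++c)
            if (H(s, c) != 0.0) input(t + k, c) += H(s, c) * h[k] * stim(t, s);
        }
      }
    }
    for (int c = 0; c < nc; ++c) {
      v[c] += dt * (-v[c] + bcur(t, c) + input(t, c));
      if (v[c] >= 1.0) {
        v[c] = 0.0;
        spikes(t, c) = 1;
        for (int k = 0; k < kernel_len && t + k < m; ++k) {
          if (h[k] == 0.0) continue;
          for (int cc = 0; cc < nc; ++cc)
            if (W(c, cc) != 0.0) input(t + k, cc) += W(c, cc) * h[k];
        }
      }
    }
  }
  return spikes;
}
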