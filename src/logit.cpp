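#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Logistic regression by iteratively reweighted least squares with
// step-halving. Returns the coefficient vector, the log-likelihood and a
// convergence flag. Used on the hot path of the causal inference test's
// replicate loop, where hundreds of thousands of fits are required.

static double loglik(const arma::vec& y, const arma::vec& eta) {
  // log L = sum y*eta - log(1 + exp(eta)), computed stably
  arma::vec lse(eta.n_elem);
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    lse[i] = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
  }
  return arma::dot(y, eta) - arma::accu(lse);
}

// [[Rcpp::export(name = ".cpp_logit_irls")]]
List cpp_logit_irls(const arma::mat& X, const arma::vec& y,
                    int maxit = 60, double tol = 1e-9) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec eta = X * beta;
  double ll = loglik(y, eta);
  bool converged = false;

  for (int it = 0; it < maxit; ++it) {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
    arma::mat Xw = X.each_col() % w;
    arma::mat info = X.t() * Xw;
    arma::vec score = X.t() * (y - mu);
    arma::vec step;
    bool ok = arma::solve(step, info, score, arma::solve_opts::likely_sympd +
                                             arma::solve_opts::no_approx);
    if (!ok) break;
    // step-halving if the likelihood does not improve
    double ll_new = ll;
    arma::vec beta_new = beta;
    double fac = 1.0;
    for (int h = 0; h < 30; ++h) {
      beta_new = beta + fac * step;
      ll_new = loglik(y, X * beta_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) break;
      fac *= 0.5;
    }
    double delta = ll_new - ll;
    beta = beta_new;
    eta = X * beta;
    ll = ll_new;
    if (std::abs(delta) < tol * (std::abs(ll) + 0.1)) {
      converged = true;
      break;
    }
  }
  arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
  double mx = mu.max(), mn = mu.min();
  bool boundary = (mx > 1.0 - 1e-8) || (mn < 1e-8);
  return List::create(_["coefficients"] = beta, _["loglik"] = ll,
                      _["converged"] = converged, _["boundary"] = boundary);
}
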