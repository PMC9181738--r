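#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Iteratively reweighted least squares for logistic regression with a
// fixed design. Used in the bootstrap hot loop, where thousands of
// warm-started refits of the same model structure are needed.
//
// Returns the coefficient vector; sets `converged` to false on failure
// (singular information or iteration cap).
// [[Rcpp::export(name = ".irls_logit")]]
Rcpp::List irls_logit(const arma::mat& X, const arma::vec& y,
                      const arma::vec& start, int maxit = 50,
                      double tol = 1e-9) {
  vec beta = start;
  double dev_old = datum::inf;
  bool ok = false;
  vec eta, mu, w, z;
  for (int it = 0; it < maxit; ++it) {
    eta = X * beta;
    mu = 1.0 / (1.0 + exp(-eta));
    mu = clamp(mu, 1e-10, 1.0 - 1e-10);
    w = mu % (1.0 - mu);
    z = eta + (y - mu) / w;
    mat XtW = X.each_col() % w;
    mat info = X.t() * XtW;
    vec rhs = XtW.t() * z;
    vec beta_new;
    if (!solve(beta_new, info, rhs, solve_opts::likely_sympd)) {
      return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                                Rcpp::Named("converged") = false);
    }
    beta = beta_new;
    double dev = -2.0 * sum(y % log(mu) + (1.0 - y) % log(1.0 - mu));
    if (std::abs(dev - dev_old) < tol * (std::abs(dev) + 0.1)) {
      ok = true;
      break;
    }
    dev_old = dev;
  }
  return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                            Rcpp::Named("converged") = ok);
}
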