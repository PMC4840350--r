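// Iteratively reweighted least squares for binomial-logit models.
// Compiled because the permutation epistasis scan refits the interaction
// model hundreds of thousands of times (pairs x permutations).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// One IRLS solve. Returns coefficients, standard errors from the observed
// information at the optimum, convergence flag, iteration count, log-likelihood.
// [[Rcpp::export(name = ".irls_logit")]]
Rcpp::List irls_logit(const arma::mat& X, const arma::vec& y,
                      double tol, int maxit) {
  const int p = X.n_cols;
  vec beta(p, fill::zeros);
  double ybar = mean(y);
  ybar = std::min(std::max(ybar, 1e-8), 1.0 - 1e-8);
  beta(0) = std::log(ybar / (1.0 - ybar));

  mat XtWX(p, p, fill::eye);
  bool conv = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    vec eta = X * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    vec z = eta + (y - mu) / w;
    mat Xw = X.each_col() % w;
    XtWX = X.t() * Xw;
    vec beta_new;
    bool ok = solve(beta_new, XtWX, Xw.t() * z,
                    solve_opts::fast + solve_opts::no_approx);
    if (!ok) { conv = false; break; }
    double d = max(abs(beta_new - beta));
    beta = beta_new;
    if (d < tol) { conv = true; break; }
  }

  vec eta = X * beta;
  vec mu = 1.0 / (1.0 + exp(-eta));
  double ll = sum(y % log(clamp(mu, 1e-12, 1.0)) +
                  (1.0 - y) % log(clamp(1.0 - mu, 1e-12, 1.0)));
  vec se(p);
  mat V;
  if (inv_sympd(V, XtWX)) {
    se = sqrt(V.diag());
  } else {
    se.fill(datum::nan);
    conv = false;
  }
  // Huge coefficients signal (quasi-)separation: the MLE is at infinity.
  if (conv && max(abs(beta)) > 15.0) conv = false;

  return Rcpp::List::create(
      Rcpp::Named("coefficients") = beta,
      Rcpp::Named("se") = se,
      Rcpp::Named("converged") = conv,
      Rcpp::Named("n_iter") = it,
      Rcpp::Named("loglik") = ll);
}

// Permutation engine for the two-locus interaction scan. For each permuted
// status vector (columns of `perm_y`, rows aligned with X), refits the model
// and returns the two-sided Wald P of column `test_col` (1-based).
// [[Rcpp::export(name = ".irls_perm_pvals")]]
arma::vec irls_perm_pvals(const arma::mat& X, const arma::mat& perm_y,
                          int test_col, double tol, int maxit) {
  const int B = perm_y.n_cols;
  vec out(B, fill::value(datum::nan));
  for (int b = 0; b < B; ++b) {
    Rcpp::List f = irls_logit(X, perm_y.col(b), tol, maxit);
    if (!Rcpp::as<bool>(f["converged"])) continue;
    vec co = f["coefficients"];
    vec se = f["se"];
    double z = co(test_col - 1) / se(test_col - 1);
    out(b) = 2.0 * R::pnorm(std::fabs(z), 0.0, 1.0, 0, 0);
  }
  return out;
}
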