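// EM for a mixture of independent Bernoulli items (binary latent class model),
// run on unique response patterns with multiplicity weights. Initial
// responsibilities are drawn in R so all randomness stays under R's RNG.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::export]]
Rcpp::List em_core(const arma::mat& X, const arma::vec& w, arma::mat tau,
                   double tol, int max_iter, double eps) {
  const double N = accu(w);
  const int K = tau.n_cols;
  mat Xc = 1.0 - X;
  vec pi(K, fill::value(1.0 / K));
  mat rho(K, X.n_cols, fill::value(0.5));
  double ll = -datum::inf, ll_old = -datum::inf;
  std::vector<double> trace;
  int it = 0;
  bool converged = false, empty_class = false;
  for (it = 1; it <= max_iter; ++it) {
    // M-step from current responsibilities
    mat wt = tau.each_col() % w;            // U x K
    rowvec nk = sum(wt, 0);
    if (nk.min() < 1e-8 * N) { empty_class = true; break; }
    pi = nk.t() / N;
    rho = wt.t() * X;                       // K x J
    rho.each_col() /= nk.t();
    rho = clamp(rho, eps, 1.0 - eps);
    // E-step in log space
    mat lp = X * log(rho).t() + Xc * log(1.0 - rho).t();
    lp.each_row() += log(pi).t();
    vec m = max(lp, 1);
    vec ls = m + log(sum(exp(lp.each_col() - m), 1));
    ll = dot(w, ls);
    trace.push_back(ll);
    tau = exp(lp.each_col() - ls);
    if (std::abs(ll - ll_old) < tol * std::abs(ll)) { converged = true; break; }
    ll_old = ll;
  }
  return Rcpp::List::create(
    Rcpp::Named("pi") = pi, Rcpp::Named("rho") = rho, Rcpp::Named("tau") = tau,
    Rcpp::Named("loglik") = ll, Rcpp::Named("trace") = trace,
    Rcpp::Named("iterations") = it, Rcpp::Named("converged") = converged,
    Rcpp::Named("empty_class") = empty_class);
}
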