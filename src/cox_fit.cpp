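// Newton solver for the Cox partial likelihood on counting-process data
// (start, stop] intervals, terminal event indicator, Efron or Breslow ties.
// Month-granularity person-period tables produce heavy ties, so Efron is
// the default throughout the package.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Accumulate loglik, gradient and (negative) Hessian at beta.
static double cox_eval(const vec& start, const vec& stop, const uvec& event,
                       const mat& X, const vec& beta, bool efron,
                       vec& grad, mat& imat) {
  const uword n = X.n_rows, p = X.n_cols;
  vec eta = X * beta;
  // guard against overflow in exp()
  eta = clamp(eta, -200.0, 200.0);
  vec w = exp(eta);

  vec etimes = sort(unique(stop.elem(find(event == 1))));
  double ll = 0.0;
  grad.zeros(p);
  imat.zeros(p, p);

  for (uword k = 0; k < etimes.n_elem; ++k) {
    double t = etimes(k);
    // risk set: start < t <= stop; deaths: event rows with stop == t
    double s0 = 0.0, s0d = 0.0;
    vec s1(p, fill::zeros), s1d(p, fill::zeros);
    mat s2(p, p, fill::zeros), s2d(p, p, fill::zeros);
    uword d = 0;
    for (uword i = 0; i < n; ++i) {
      if (start(i) < t && t <= stop(i)) {
        rowvec xi = X.row(i);
        s0 += w(i);
        s1 += w(i) * xi.t();
        s2 += w(i) * (xi.t() * xi);
        if (event(i) == 1 && stop(i) == t) {
          ++d;
          ll += eta(i);
          grad += xi.t();
          s0d += w(i);
          s1d += w(i) * xi.t();
          s2d += w(i) * (xi.t() * xi);
        }
      }
    }
    if (d == 0) continue;
    for (uword r = 0; r < d; ++r) {
      double f = efron ? (double)r / (double)d : 0.0;
      double den = s0 - f * s0d;
      vec m = (s1 - f * s1d) / den;
      ll -= std::log(den);
      grad -= m;
      imat += (s2 - f * s2d) / den - m * m.t();
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".cox_fit_cpp")]]
Rcpp::List cox_fit_cpp(Rcpp::NumericVector start_, Rcpp::NumericVector stop_,
                       Rcpp::IntegerVector event_, Rcpp::NumericMatrix X_,
                       Rcpp::NumericVector init_, int max_iter, double eps,
                       bool efron) {
  vec start(start_.begin(), start_.size(), false);
  vec stop(stop_.begin(), stop_.size(), false);
  uvec event = Rcpp::as<uvec>(event_);
  mat X(X_.begin(), X_.nrow(), X_.ncol(), false);
  vec beta = Rcpp::as<vec>(init_);
  const uword p = X.n_cols;

  vec grad(p);
  mat imat(p, p);
  double ll = cox_eval(start, stop, event, X, beta, efron, grad, imat);
  double ll0 = ll;
  bool converged = false, singular = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    if (norm(grad, "inf") < eps) { converged = true; break; }
    vec step;
    bool ok = solve(step, imat, grad, solve_opts::no_approx);
    if (!ok || !step.is_finite()) { singular = true; break; }
    // step-halving: insist the partial likelihood does not decrease
    double halving = 1.0;
    vec beta_new;
    double ll_new;
    vec grad_new(p);
    mat imat_new(p, p);
    int h;
    for (h = 0; h < 30; ++h) {
      beta_new = beta + halving * step;
      ll_new = cox_eval(start, stop, event, X, beta_new, efron, grad_new, imat_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) break;
      halving /= 2.0;
    }
    if (h == 30) break; // cannot improve
    double dll = ll_new - ll;
    beta = beta_new;
    ll = ll_new;
    grad = grad_new;
    imat = imat_new;
    // flat-direction safeguard: likelihood has stopped moving and the
    // gradient is numerically negligible relative to it
    if (dll < 1e-10 * (std::abs(ll) + 1.0) && norm(grad, "inf") < 1e-4) {
      converged = true;
      ++iter;
      break;
    }
  }
  if (!converged && norm(grad, "inf") < eps) converged = true;

  return Rcpp::List::create(
    Rcpp::Named("coef") = beta,
    Rcpp::Named("loglik0") = ll0,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("gradient") = grad,
    Rcpp::Named("imat") = imat,
    Rcpp::Named("iter") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("singular") = singular);
}
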