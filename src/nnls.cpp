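// Lawson-Hanson active-set solver for min ||Ax - b|| s.t. x >= 0.
// Used by the pupil deconvolution to estimate non-negative event
// amplitudes of PRF regressors.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& b,
                    double tol = -1.0, int max_iter = -1) {
  const int n = A.n_cols;
  if (max_iter < 0) max_iter = 3 * n + 30;
  vec x = zeros(n);
  std::vector<bool> passive(n, false);
  vec w = A.t() * b;                 // gradient of -0.5||Ax-b||^2 at x = 0
  if (tol < 0) tol = 1e-10 * std::max(1.0, norm(w, "inf"));

  int outer = 0;
  while (outer++ < max_iter) {
    // most violated KKT condition among active (zero) coordinates
    int t = -1;
    double wmax = tol;
    for (int j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = j; }
    }
    if (t < 0) break;                // KKT satisfied
    passive[t] = true;

    int inner = 0;
    while (inner++ < max_iter) {
      uvec pidx(n);
      int np = 0;
      for (int j = 0; j < n; ++j) if (passive[j]) pidx(np++) = j;
      pidx.resize(np);
      mat Ap = A.cols(pidx);
      vec z;
      bool ok = solve(z, Ap, b);     // least squares on the passive set
      if (!ok) Rcpp::stop("nnls: least-squares subproblem failed");

      if (z.min() > 0) {
        x.zeros();
        for (int j = 0; j < np; ++j) x(pidx(j)) = z(j);
        break;
      }
      // step towards z until the first passive coordinate hits zero
      double alpha = datum::inf;
      for (int j = 0; j < np; ++j) {
        if (z(j) <= 0) {
          double a = x(pidx(j)) / (x(pidx(j)) - z(j));
          if (a < alpha) alpha = a;
        }
      }
      for (int j = 0; j < np; ++j) {
        double xn = x(pidx(j)) + alpha * (z(j) - x(pidx(j)));
        x(pidx(j)) = xn;
        if (xn <= 1e-12) { x(pidx(j)) = 0.0; passive[pidx(j)] = false; }
      }
    }
    w = A.t() * (b - A * x);
  }
  vec resid = b - A * x;
  return Rcpp::List::create(
    Rcpp::Named("x") = x,
    Rcpp::Named("rss") = dot(resid, resid),
    Rcpp::Named("gradient") = A.t() * resid);
}
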