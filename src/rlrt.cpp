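#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Restricted-LRT criterion in the spectral basis:
//   f(lambda) = dof * log(S(0) / S(lambda)) - sum_s log(1 + lambda * xi_s)
// with S(lambda) = sum_{s<=K} u_s^2 / (1 + lambda xi_s) + tail2.
// f(0) = 0 by construction; the RLRT statistic is sup_{lambda>=0} f, clipped at 0.
static inline double rlrt_crit(double lam, const double* u2, const double* xi,
                               int K, double tail2, double dof, double S0) {
  double S = tail2, ld = 0.0;
  for (int s = 0; s < K; ++s) {
    double d = 1.0 + lam * xi[s];
    S += u2[s] / d;
    ld += std::log(d);
  }
  return dof * std::log(S0 / S) - ld;
}

// Batched sup over lambda >= 0 of the restricted-LRT criterion.
//
// u2     : K x B matrix of squared rotated coefficients (one column per draw)
// tail2  : length-B vector of squared norms of the residual tail (dof - K dims)
// xi     : K positive eigenvalues of Z' P0 Z, descending
// dof    : n - q
// grid   : strictly positive lambda grid, ascending (lambda = 0 is implicit)
// refine_iter : golden-section iterations inside the bracketing interval
// zero_tol    : statistics below this are snapped to 0 (lambda_hat = 0)
//
// Returns T (clipped sup) and lambda_hat per draw. The identical search is
// used for observed statistics and for null-distribution draws so both share
// the same discretization.
// [[Rcpp::export]]
Rcpp::List cpp_sup_rlrt(const arma::mat& u2, const arma::vec& tail2,
                        const arma::vec& xi, double dof,
                        const arma::vec& grid, int refine_iter,
                        double zero_tol) {
  const int K = u2.n_rows;
  const int B = u2.n_cols;
  const int G = grid.n_elem;

  vec Tstat(B, fill::zeros), lam_hat(B, fill::zeros);
  if (K == 0 || B == 0) {
    return Rcpp::List::create(Rcpp::Named("T") = Tstat,
                              Rcpp::Named("lambda") = lam_hat);
  }

  rowvec S0 = sum(u2, 0) + tail2.t();

  // grid pass: best criterion value and grid index per draw (index -1 <=> 0)
  vec best_val(B, fill::zeros);
  ivec best_idx(B);
  best_idx.fill(-1);
  for (int g = 0; g < G; ++g) {
    vec c = 1.0 / (1.0 + grid[g] * xi);
    double logdet = accu(log(1.0 + grid[g] * xi));
    rowvec S = c.t() * u2 + tail2.t();
    for (int b = 0; b < B; ++b) {
      double f = dof * std::log(S0[b] / S[b]) - logdet;
      if (f > best_val[b]) { best_val[b] = f; best_idx[b] = g; }
    }
  }

  const double golden = 0.5 * (std::sqrt(5.0) - 1.0);
  for (int b = 0; b < B; ++b) {
    int i = best_idx[b];
    if (i < 0) continue;  // boundary maximum at lambda = 0
    double lo = (i == 0) ? 0.0 : grid[i - 1];
    double hi = (i == G - 1) ? grid[G - 1] : grid[i + 1];
    const double* u2b = u2.colptr(b);
    const double* xip = xi.memptr();
    double fbest = best_val[b], lbest = grid[i];

    if (hi > lo) {
      double a = lo, c = hi;
      double x1 = c - golden * (c - a);
      double x2 = a + golden * (c - a);
      double f1 = rlrt_crit(x1, u2b, xip, K, tail2[b], dof, S0[b]);
      double f2 = rlrt_crit(x2, u2b, xip, K, tail2[b], dof, S0[b]);
      for (int it = 0; it < refine_iter; ++it) {
        if (f1 > f2) {
          c = x2; x2 = x1; f2 = f1;
          x1 = c - golden * (c - a);
          f1 = rlrt_crit(x1, u2b, xip, K, tail2[b], dof, S0[b]);
        } else {
          a = x1; x1 = x2; f1 = f2;
          x2 = a + golden * (c - a);
          f2 = rlrt_crit(x2, u2b, xip, K, tail2[b], dof, S0[b]);
        }
      }
      if (f1 > fbest) { fbest = f1; lbest = x1; }
      if (f2 > fbest) { fbest = f2; lbest = x2; }
    }

    if (fbest <= zero_tol) {
      Tstat[b] = 0.0; lam_hat[b] = 0.0;
    } else {
      Tstat[b] = fbest; lam_hat[b] = lbest;
    }
  }

  return Rcpp::List::create(Rcpp::Named("T") = Tstat,
                            Rcpp::Named("lambda") = lam_hat);
}
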