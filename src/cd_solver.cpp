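#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Elastic-net penalized weighted least squares by cyclic coordinate descent.
//
// Minimizes
//   0.5 * sum_i w_i (z_i - b0 - x_i' b)^2
//     + lambda * ( alpha * ||b||_1 + 0.5 * (1 - alpha) * ||b||_2^2 )
// over (b0, b); the intercept b0 is never penalized.  This is the quadratic
// subproblem of the proximal-Newton outer loops (penalized logistic experts
// and the soft-label multinomial gating network), so it is the hot path.
//
// beta_init has length p + 1 with the intercept first; the residual vector is
// maintained incrementally so each coordinate update is O(n).
// [[Rcpp::export]]
List cd_wls(const NumericMatrix& X, const NumericVector& z,
            const NumericVector& w, double lambda, double alpha,
            const NumericVector& beta_init, double tol, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector b = clone(beta_init);
  std::vector<double> r(n);

  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += w[i];

  for (int i = 0; i < n; ++i) {
    double eta = b[0];
    for (int j = 0; j < p; ++j) eta += X(i, j) * b[j + 1];
    r[i] = z[i] - eta;
  }

  // curvature sum_i w_i x_ij^2 is constant across sweeps
  std::vector<double> xwx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
    xwx[j] = s;
  }

  const double l1 = lambda * alpha;
  const double l2 = lambda * (1.0 - alpha);
  bool converged = false;
  int sweep = 0;

  for (; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;

    if (wsum > 0.0) {
      double num0 = 0.0;
      for (int i = 0; i < n; ++i) num0 += w[i] * r[i];
      double d0 = num0 / wsum;
      if (d0 != 0.0) {
        b[0] += d0;
        for (int i = 0; i < n; ++i) r[i] -= d0;
        max_delta = std::max(max_delta, std::fabs(d0));
      }
    }

    for (int j = 0; j < p; ++j) {
      if (xwx[j] + l2 <= 0.0) continue;
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += w[i] * X(i, j) * r[i];
      double u = g + xwx[j] * b[j + 1];
      double b_new = soft_threshold(u, l1) / (xwx[j] + l2);
      double d = b_new - b[j + 1];
      if (d != 0.0) {
        b[j + 1] = b_new;
        for (int i = 0; i < n; ++i) r[i] -= d * X(i, j);
        max_delta = std::max(max_delta, std::fabs(d));
      }
    }

    if (max_delta < tol) { converged = true; ++sweep; break; }
  }

  return List::create(_["beta"] = b,
                      _["converged"] = converged,
                      _["sweeps"] = sweep);
}
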