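#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Log-domain semi-relaxed Sinkhorn iteration for the gap-augmented partial
// assignment. logK is the (m+1) x (n+1) matrix -lambda * C with the
// gap-to-gap corner set to -Inf (it belongs to no constrained margin).
// Constrained margins: rows 0..m-1 (sum over all n+1 columns = 1) and
// columns 0..n-1 (sum over all m+1 rows = 1); the gap row/column duals are
// frozen at zero. One iteration = row scaling then column scaling; the
// row-feasibility violation after column scaling equals
// max_i |exp(f_i - f_i') - 1| with f' the recomputed row duals, so each
// iteration costs exactly two log-sum-exp passes. On a tentative pass the
// column margin is verified explicitly before declaring convergence.
//
// [[Rcpp::export(name = ".sinkhorn_loop")]]
List sinkhorn_loop(const NumericMatrix& logK, int m, int n, double tol,
                   int tmax) {
  const double NEG_INF = -std::numeric_limits<double>::infinity();
  std::vector<double> f(m, 0.0), g(n, 0.0), fnew(m, 0.0);
  int it = 0;
  bool converged = false;

  auto lse_row = [&](int i) {
    // log sum_j exp(logK(i, j) + g_aug(j)) over j = 0..n (gap dual = 0)
    double mx = NEG_INF;
    for (int j = 0; j <= n; ++j) {
      double v = logK(i, j) + (j < n ? g[j] : 0.0);
      if (v > mx) mx = v;
    }
    if (mx == NEG_INF) return NEG_INF;
    double s = 0.0;
    for (int j = 0; j <= n; ++j) {
      double v = logK(i, j) + (j < n ? g[j] : 0.0);
      if (v > NEG_INF) s += std::exp(v - mx);
    }
    return mx + std::log(s);
  };
  auto lse_col = [&](int j) {
    double mx = NEG_INF;
    for (int i = 0; i <= m; ++i) {
      double v = logK(i, j) + (i < m ? f[i] : 0.0);
      if (v > mx) mx = v;
    }
    if (mx == NEG_INF) return NEG_INF;
    double s = 0.0;
    for (int i = 0; i <= m; ++i) {
      double v = logK(i, j) + (i < m ? f[i] : 0.0);
      if (v > NEG_INF) s += std::exp(v - mx);
    }
    return mx + std::log(s);
  };

  for (int i = 0; i < m; ++i) f[i] = -lse_row(i);

  for (it = 1; it <= tmax; ++it) {
    for (int j = 0; j < n; ++j) g[j] = -lse_col(j);
    double viol = 0.0;
    for (int i = 0; i < m; ++i) {
      fnew[i] = -lse_row(i);
      double v = std::fabs(std::exp(f[i] - fnew[i]) - 1.0);
      if (v > viol) viol = v;
    }
    f = fnew;
    if (viol < tol) {
      double cviol = 0.0;
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int i = 0; i <= m; ++i) {
          double v = logK(i, j) + (i < m ? f[i] : 0.0) + g[j];
          if (v > NEG_INF) s += std::exp(v);
        }
        double cv = std::fabs(s - 1.0);
        if (cv > cviol) cviol = cv;
      }
      if (cviol < tol) {
        converged = true;
        break;
      }
    }
  }
  if (it > tmax) it = tmax;

  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["g"] = NumericVector(g.begin(), g.end()),
                      _["iterations"] = it, _["converged"] = converged);
}
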