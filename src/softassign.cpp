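#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-assignment update of deterministic-annealing RPM: builds
// m_ij = exp(-d2_ij / (2T)) augmented with an outlier slack row/column
// (entries `slack`, corner 0), then alternates row/column normalization
// for `iters` sweeps. The slack row and column are not normalized
// themselves (softassign convention). Returns the (n+1) x (k+1) matrix.
// [[Rcpp::export(name = ".softassign")]]
NumericMatrix softassign(NumericMatrix d2, double temp, double slack,
                         int iters) {
  int n = d2.nrow(), k = d2.ncol();
  int nr = n + 1, nc = k + 1;
  NumericMatrix m(nr, nc);
  double *pm = REAL(m);
  const double *pd = REAL(d2);
  double inv2t = 1.0 / (2.0 * temp);
  for (int j = 0; j < k; ++j) {
    double *col = pm + (R_xlen_t)j * nr;
    const double *dcol = pd + (R_xlen_t)j * n;
    for (int i = 0; i < n; ++i) col[i] = std::exp(-dcol[i] * inv2t);
    col[n] = slack;
  }
  double *last = pm + (R_xlen_t)k * nr;
  for (int i = 0; i < n; ++i) last[i] = slack;
  last[n] = 0.0;
  std::vector<double> rs(n);
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) rs[i] = 0.0;
    for (int j = 0; j < nc; ++j) {
      const double *col = pm + (R_xlen_t)j * nr;
      for (int i = 0; i < n; ++i) rs[i] += col[i];
    }
    for (int i = 0; i < n; ++i) rs[i] = 1.0 / rs[i];
    for (int j = 0; j < nc; ++j) {
      double *col = pm + (R_xlen_t)j * nr;
      for (int i = 0; i < n; ++i) col[i] *= rs[i];
    }
    for (int j = 0; j < k; ++j) {
      double *col = pm + (R_xlen_t)j * nr;
      double s = 0.0;
      for (int i = 0; i < nr; ++i) s += col[i];
      s = 1.0 / s;
      for (int i = 0; i < nr; ++i) col[i] *= s;
    }
  }
  return m;
}
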