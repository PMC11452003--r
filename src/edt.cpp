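#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared Euclidean distance transform (lower envelope of parabolas),
// sampled on a uniform grid with physical step `w`. Positions with f = +Inf
// carry no parabola; the line must contain at least one finite value.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  int k = -1; // index of the rightmost parabola in the envelope
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s > z[k]) break;
      k--;
      if (k < 0) break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      k++; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in mm^2, honouring per-axis spacing)
// from every voxel to the nearest TRUE voxel centre. Voxels with no TRUE
// site anywhere come back +Inf.
// [[Rcpp::export]]
NumericVector edt_squared(LogicalVector sites, IntegerVector dims,
                          NumericVector spacing) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = sites[i] ? 0.0 : INF;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax);

  // axis 1 (fastest varying)
  for (int k = 0; k < d3; k++)
    for (int j = 0; j < d2; j++) {
      R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
      bool any = false;
      for (int i = 0; i < d1; i++) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, d1, spacing[0]);
      for (int i = 0; i < d1; i++) out[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < d3; k++)
    for (int i = 0; i < d1; i++) {
      R_xlen_t base = i + (R_xlen_t)d1 * d2 * k;
      bool any = false;
      for (int j = 0; j < d2; j++) { f[j] = out[base + (R_xlen_t)d1 * j]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, d2, spacing[1]);
      for (int j = 0; j < d2; j++) out[base + (R_xlen_t)d1 * j] = d[j];
    }
  // axis 3
  R_xlen_t plane = (R_xlen_t)d1 * d2;
  for (int j = 0; j < d2; j++)
    for (int i = 0; i < d1; i++) {
      R_xlen_t base = i + (R_xlen_t)d1 * j;
      bool any = false;
      for (int k = 0; k < d3; k++) { f[k] = out[base + plane * k]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, d3, spacing[2]);
      for (int k = 0; k < d3; k++) out[base + plane * k] = d[k];
    }
  return out;
}
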