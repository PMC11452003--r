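#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sample_tri(const double* v, int d1, int d2, int d3,
                                double x, double y, double z, double outside) {
  // x,y,z are 0-based voxel coordinates
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > d1 - 0.5 || y > d2 - 0.5 || z > d3 - 0.5)
    return outside;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; dk++) {
    int k = k0 + dk;
    double wz = dk ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dj = 0; dj <= 1; dj++) {
      int j = j0 + dj;
      double wy = dj ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int di = 0; di <= 1; di++) {
        int i = i0 + di;
        double wx = di ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        double val = outside;
        if (i >= 0 && j >= 0 && k >= 0 && i < d1 && j < d2 && k < d3)
          val = v[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
        acc += wx * wy * wz * val;
      }
    }
  }
  return acc;
}

// Trilinear interpolation of a 3D volume at 0-based voxel coordinates.
// [[Rcpp::export]]
NumericVector trilinear_sample(NumericVector vol, IntegerVector dims,
                               NumericMatrix pts, double outside = 0.0) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (int q = 0; q < n; q++)
    out[q] = sample_tri(v, d1, d2, d3, pts(q, 0), pts(q, 1), pts(q, 2), outside);
  return out;
}

// Separable Gaussian smoothing, sigma in voxels per axis, zero padding,
// kernel truncated at 3 sigma and normalised to unit sum.
// [[Rcpp::export]]
NumericVector gauss_smooth3(NumericVector vol, IntegerVector dims,
                            NumericVector sigma) {
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  std::vector<double> cur(vol.begin(), vol.end()), nxt(n);
  R_xlen_t stride[3] = {1, (R_xlen_t)d[0], (R_xlen_t)d[0] * d[1]};
  for (int ax = 0; ax < 3; ax++) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; t++) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); tot += ker[t + r]; }
    for (int t = 0; t <= 2 * r; t++) ker[t] /= tot;
    int len = d[ax];
    R_xlen_t st = stride[ax];
    // iterate over all lines along this axis
    for (int k = 0; k < (ax == 2 ? 1 : d[2]); k++)
      for (int j = 0; j < (ax == 1 ? 1 : d[1]); j++)
        for (int i = 0; i < (ax == 0 ? 1 : d[0]); i++) {
          R_xlen_t base = i * stride[0] + (R_xlen_t)j * stride[1] + (R_xlen_t)k * stride[2];
          for (int q = 0; q < len; q++) {
            double acc = 0;
            int lo = std::max(0, q - r), hi = std::min(len - 1, q + r);
            for (int t = lo; t <= hi; t++)
              acc += ker[t - q + r] * cur[base + (R_xlen_t)t * st];
            nxt[base + (R_xlen_t)q * st] = acc;
          }
        }
    cur.swap(nxt);
  }
  NumericVector out(n);
  std::copy(cur.begin(), cur.end(), out.begin());
  return out;
}

// Brute-force nearest neighbour of each query point among reference points.
// Returns 1-based indices and squared distances.
// [[Rcpp::export]]
List nn_bruteforce(NumericMatrix query, NumericMatrix ref) {
  int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  NumericVector d2(n);
  for (int q = 0; q < n; q++) {
    double best = R_PosInf;
    int bi = 0;
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    for (int r = 0; r < m; r++) {
      double dx = qx - ref(r, 0), dy = qy - ref(r, 1), dz = qz - ref(r, 2);
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) { best = dd; bi = r; }
    }
    idx[q] = bi + 1;
    d2[q] = best;
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}

// Moving sum over a w x w window ("same" size, zero padding) of a 2D
// integer-valued image; exact integer arithmetic.
// [[Rcpp::export]]
IntegerMatrix box_sum2d(IntegerMatrix img, int w) {
  int nr = img.nrow(), nc = img.ncol();
  int r = w / 2;       // for odd w the window is centred
  int rlo = r, rhi = w - 1 - r;
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) {
      int acc = 0;
      for (int dj = -rlo; dj <= rhi; dj++) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -rlo; di <= rhi; di++) {
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          acc += img(ii, jj);
        }
      }
      out(i, j) = acc;
    }
  return out;
}
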