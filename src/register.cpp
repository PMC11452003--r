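#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared helper: trilinear weights of a point within the node grid, with
// clamping to the grid extent (out-of-box queries take the nearest node).
struct CellW {
  int idx[8];
  double w[8];
};

static inline void node_cell(double tx, double ty, double tz,
                             int n1, int n2, int n3, CellW& cw) {
  if (tx < 0) tx = 0; if (tx > n1 - 1) tx = n1 - 1;
  if (ty < 0) ty = 0; if (ty > n2 - 1) ty = n2 - 1;
  if (tz < 0) tz = 0; if (tz > n3 - 1) tz = n3 - 1;
  int i0 = (int)std::floor(tx); if (i0 > n1 - 2) i0 = std::max(0, n1 - 2);
  int j0 = (int)std::floor(ty); if (j0 > n2 - 2) j0 = std::max(0, n2 - 2);
  int k0 = (int)std::floor(tz); if (k0 > n3 - 2) k0 = std::max(0, n3 - 2);
  double fx = tx - i0, fy = ty - j0, fz = tz - k0;
  int q = 0;
  for (int dk = 0; dk <= 1; dk++)
    for (int dj = 0; dj <= 1; dj++)
      for (int di = 0; di <= 1; di++) {
        int i = std::min(i0 + di, n1 - 1);
        int j = std::min(j0 + dj, n2 - 1);
        int k = std::min(k0 + dk, n3 - 1);
        cw.idx[q] = i + n1 * (j + n2 * k);
        cw.w[q] = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        q++;
      }
}

static inline double tri3(const double* v, int d1, int d2, int d3,
                          double x, double y, double z) {
  // zero outside
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > d1 - 0.5 || y > d2 - 0.5 || z > d3 - 0.5)
    return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; dk++) {
    int k = k0 + dk;
    double wz = dk ? fz : 1 - fz;
    if (wz == 0) continue;
    for (int dj = 0; dj <= 1; dj++) {
      int j = j0 + dj;
      double wy = dj ? fy : 1 - fy;
      if (wy == 0) continue;
      for (int di = 0; di <= 1; di++) {
        int i = i0 + di;
        double wx = di ? fx : 1 - fx;
        if (wx == 0) continue;
        if (i >= 0 && j >= 0 && k >= 0 && i < d1 && j < d2 && k < d3)
          acc += wx * wy * wz * v[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
      }
    }
  }
  return acc;
}

// SSD cost (+ optional gradient) of the nodal-grid registration:
//   C(u) = sum_x (F(x) - M(x + u(x)))^2 + lambda * sum_nodes |Lap u|^2
// u is K x 3 (voxel units), nodes on a grid with spacing ns voxels whose
// node (0,0,0) sits at voxel coordinate node0. Lap is the node-graph
// Laplacian over 6-neighbour nodes.
// [[Rcpp::export]]
List reg_cost_grad(NumericVector F, NumericVector M,
                   NumericVector Gx, NumericVector Gy, NumericVector Gz,
                   IntegerVector dims, NumericMatrix u,
                   IntegerVector ndims, NumericVector node0, double ns,
                   double lambda, bool want_grad) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n1 = ndims[0], n2 = ndims[1], n3 = ndims[2];
  int K = n1 * n2 * n3;
  const double* pF = REAL(F);
  const double* pM = REAL(M);
  const double* pGx = want_grad ? REAL(Gx) : nullptr;
  const double* pGy = want_grad ? REAL(Gy) : nullptr;
  const double* pGz = want_grad ? REAL(Gz) : nullptr;
  NumericMatrix grad(want_grad ? K : 1, 3);
  double ssd = 0.0;
  CellW cw;
  for (int k = 0; k < d3; k++)
    for (int j = 0; j < d2; j++)
      for (int i = 0; i < d1; i++) {
        node_cell((i - node0[0]) / ns, (j - node0[1]) / ns,
                  (k - node0[2]) / ns, n1, n2, n3, cw);
        double ux = 0, uy = 0, uz = 0;
        for (int q = 0; q < 8; q++) {
          ux += cw.w[q] * u(cw.idx[q], 0);
          uy += cw.w[q] * u(cw.idx[q], 1);
          uz += cw.w[q] * u(cw.idx[q], 2);
        }
        double x = i + ux, y = j + uy, z = k + uz;
        double m = tri3(pM, d1, d2, d3, x, y, z);
        double r = pF[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] - m;
        ssd += r * r;
        if (want_grad && r != 0.0) {
          double gx = tri3(pGx, d1, d2, d3, x, y, z);
          double gy = tri3(pGy, d1, d2, d3, x, y, z);
          double gz = tri3(pGz, d1, d2, d3, x, y, z);
          double c = -2.0 * r;
          for (int q = 0; q < 8; q++) {
            grad(cw.idx[q], 0) += c * cw.w[q] * gx;
            grad(cw.idx[q], 1) += c * cw.w[q] * gy;
            grad(cw.idx[q], 2) += c * cw.w[q] * gz;
          }
        }
      }
  // smoothness penalty and its gradient
  std::vector<double> lap(3 * (R_xlen_t)K, 0.0);
  std::vector<int> deg(K, 0);
  double pen = 0.0;
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        int n = i + n1 * (j + n2 * k);
        double lx = 0, ly = 0, lz = 0;
        int dg = 0;
        const int di[6] = {1, -1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, 1, -1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, 1, -1};
        for (int t = 0; t < 6; t++) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
            continue;
          int nb = ii + n1 * (jj + n2 * kk);
          lx += u(nb, 0) - u(n, 0);
          ly += u(nb, 1) - u(n, 1);
          lz += u(nb, 2) - u(n, 2);
          dg++;
        }
        lap[n] = lx; lap[K + n] = ly; lap[2 * (R_xlen_t)K + n] = lz;
        deg[n] = dg;
        pen += lx * lx + ly * ly + lz * lz;
      }
  if (want_grad && lambda > 0) {
    for (int k = 0; k < n3; k++)
      for (int j = 0; j < n2; j++)
        for (int i = 0; i < n1; i++) {
          int n = i + n1 * (j + n2 * k);
          double ax = -deg[n] * lap[n];
          double ay = -deg[n] * lap[K + n];
          double az = -deg[n] * lap[2 * (R_xlen_t)K + n];
          const int di[6] = {1, -1, 0, 0, 0, 0};
          const int dj[6] = {0, 0, 1, -1, 0, 0};
          const int dk[6] = {0, 0, 0, 0, 1, -1};
          for (int t = 0; t < 6; t++) {
            int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
              continue;
            int nb = ii + n1 * (jj + n2 * kk);
            ax += lap[nb];
            ay += lap[K + nb];
            az += lap[2 * (R_xlen_t)K + nb];
          }
          grad(n, 0) += 2.0 * lambda * ax;
          grad(n, 1) += 2.0 * lambda * ay;
          grad(n, 2) += 2.0 * lambda * az;
        }
  }
  return List::create(_["cost"] = ssd + lambda * pen, _["ssd"] = ssd,
                      _["penalty"] = pen,
                      _["grad"] = want_grad ? (SEXP)grad : R_NilValue);
}

// Dense displacement (voxel units) of every voxel of a d1 x d2 x d3 box,
// trilinearly interpolated from the node grid. Returns an (nvox x 3) matrix
// in column-major voxel order.
// [[Rcpp::export]]
NumericMatrix dense_field_cpp(NumericMatrix u, IntegerVector ndims,
                              NumericVector node0, double ns,
                              IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n1 = ndims[0], n2 = ndims[1], n3 = ndims[2];
  R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;
  NumericMatrix out(nvox, 3);
  CellW cw;
  R_xlen_t q = 0;
  for (int k = 0; k < d3; k++)
    for (int j = 0; j < d2; j++)
      for (int i = 0; i < d1; i++, q++) {
        node_cell((i - node0[0]) / ns, (j - node0[1]) / ns,
                  (k - node0[2]) / ns, n1, n2, n3, cw);
        double ux = 0, uy = 0, uz = 0;
        for (int t = 0; t < 8; t++) {
          ux += cw.w[t] * u(cw.idx[t], 0);
          uy += cw.w[t] * u(cw.idx[t], 1);
          uz += cw.w[t] * u(cw.idx[t], 2);
        }
        out(q, 0) = ux; out(q, 1) = uy; out(q, 2) = uz;
      }
  return out;
}
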