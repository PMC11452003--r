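#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double pair_kernel(double dx, double dy, double dI,
                                 double W1, double ta2, double tb2,
                                 double W2, double tg2) {
  double dp2 = dx * dx + dy * dy;
  return W1 * std::exp(-dp2 / (2.0 * ta2) - dI * dI / (2.0 * tb2)) +
         W2 * std::exp(-dp2 / (2.0 * tg2));
}

// Exact Gibbs energy of a labelling: sum of unary terms -log p_i(x_i) plus
// Potts pairwise terms k(i,j)*[x_i != x_j] over all unordered pixel pairs.
// labels are 0-based.
// [[Rcpp::export]]
double crf_gibbs_energy_cpp(IntegerVector labels, NumericMatrix unary,
                            NumericMatrix pos, NumericVector intensity,
                            double W1, double ta, double tb,
                            double W2, double tg) {
  int n = labels.size();
  double ta2 = ta * ta, tb2 = tb * tb, tg2 = tg * tg;
  double E = 0.0;
  for (int i = 0; i < n; i++) {
    double p = unary(i, labels[i]);
    if (p <= 0.0) return R_PosInf;
    E -= std::log(p);
  }
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) {
      if (labels[i] == labels[j]) continue;
      E += pair_kernel(pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1),
                       intensity[i] - intensity[j], W1, ta2, tb2, W2, tg2);
    }
  return E;
}

// Mean-field inference for the fully connected CRF with Potts compatibility,
// exact O(n^2) pairwise messages, synchronous updates:
//   Q_i(l) <- (1/Z_i) p_i(l) * exp( -sum_{j!=i} k(i,j) * (1 - Q_j(l)) )
// [[Rcpp::export]]
NumericMatrix crf_mean_field_cpp(NumericMatrix unary, NumericMatrix pos,
                                 NumericVector intensity,
                                 double W1, double ta, double tb,
                                 double W2, double tg, int iters) {
  int n = unary.nrow(), L = unary.ncol();
  double ta2 = ta * ta, tb2 = tb * tb, tg2 = tg * tg;
  NumericMatrix Q(n, L);
  for (int i = 0; i < n; i++)
    for (int l = 0; l < L; l++) Q(i, l) = unary(i, l);
  std::vector<double> msg((size_t)n * L), ksum(n);
  for (int it = 0; it < iters; it++) {
    std::fill(msg.begin(), msg.end(), 0.0);
    std::fill(ksum.begin(), ksum.end(), 0.0);
    // the kernel is symmetric: accumulate each unordered pair once
    for (int i = 0; i < n; i++) {
      double xi = pos(i, 0), yi = pos(i, 1), Ii = intensity[i];
      for (int j = i + 1; j < n; j++) {
        double k = pair_kernel(xi - pos(j, 0), yi - pos(j, 1),
                               Ii - intensity[j], W1, ta2, tb2, W2, tg2);
        ksum[i] += k;
        ksum[j] += k;
        for (int l = 0; l < L; l++) {
          msg[(size_t)i * L + l] += k * Q(j, l);
          msg[(size_t)j * L + l] += k * Q(i, l);
        }
      }
    }
    std::vector<double> qn(L);
    for (int i = 0; i < n; i++) { // synchronous update
      double z = 0.0;
      for (int l = 0; l < L; l++) {
        double pen = ksum[i] - msg[(size_t)i * L + l]; // sum_j k (1 - Q_j(l))
        double v = unary(i, l) * std::exp(-pen);
        qn[l] = v;
        z += v;
      }
      if (z <= 0.0) { // all mass vanished numerically: fall back to unary
        for (int l = 0; l < L; l++) Q(i, l) = unary(i, l);
      } else {
        for (int l = 0; l < L; l++) Q(i, l) = qn[l] / z;
      }
    }
  }
  return Q;
}
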