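#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling on a 3D logical array (pass d3 = 1 for 2D
// slices). connectivity: 6 or 26 in 3D; 4 or 8 restrict moves to the first
// two axes. Components are numbered 1.. in scan order (column-major), so the
// labelling is deterministic.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n); // zero-initialised
  std::vector<int> offs_i, offs_j, offs_k;
  bool planar = (connectivity == 4 || connectivity == 8);
  bool full = (connectivity == 8 || connectivity == 26);
  for (int dk = -1; dk <= 1; dk++) {
    if (planar && dk != 0) continue;
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (!full && manh != 1) continue;
        offs_i.push_back(di); offs_j.push_back(dj); offs_k.push_back(dk);
      }
  }
  int noffs = (int)offs_i.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % d1);
      int j = (int)((cur / d1) % d2);
      int k = (int)(cur / ((R_xlen_t)d1 * d2));
      for (int t = 0; t < noffs; t++) {
        int ii = i + offs_i[t], jj = j + offs_j[t], kk = k + offs_k[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
          continue;
        R_xlen_t idx = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  return lab;
}
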