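#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a binary matrix by breadth-first flood
// fill. Labels are assigned 1..k in raster-scan order of each component's
// first pixel, so label ids are deterministic for a given mask.
// connectivity: 4 (edge neighbours) or 8 (edge + diagonal neighbours).
// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
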