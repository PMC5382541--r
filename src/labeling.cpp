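#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary raster.
// Labels are dense 1..n, assigned in row-major first-pixel order (scan rows
// top to bottom, columns left to right), so the labeling is deterministic
// and independent of any library internals.
//
// connectivity: 4 (rook) or 8 (queen).
// Returns list(labels = IntegerMatrix, sizes = IntegerVector of pixel counts).
// [[Rcpp::export(name = ".label_cc")]]
List label_cc(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> sizes;
  std::vector<int> stack_r, stack_c;
  stack_r.reserve(256);
  stack_c.reserve(256);

  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;

  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next;
      int count = 0;
      stack_r.clear();
      stack_c.clear();
      stack_r.push_back(r);
      stack_c.push_back(c);
      labels(r, c) = next;
      while (!stack_r.empty()) {
        int pr = stack_r.back(); stack_r.pop_back();
        int pc = stack_c.back(); stack_c.pop_back();
        ++count;
        for (int k = 0; k < nnb; ++k) {
          int qr = pr + dr8[k], qc = pc + dc8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && labels(qr, qc) == 0) {
            labels(qr, qc) = next;
            stack_r.push_back(qr);
            stack_c.push_back(qc);
          }
        }
      }
      sizes.push_back(count);
    }
  }
  return List::create(_["labels"] = labels,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}
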