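#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labeling of a logical mask by iterative flood fill.
// connectivity 4: edge-sharing neighbours; 8: edge- or corner-sharing.
// Labels are assigned in raster (column-major) order of first encounter,
// so the labeling is deterministic.
// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int nn = connectivity;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (!mask(qr, qc) || lab(qr, qc) != 0) continue;
          lab(qr, qc) = next;
          stack.push_back(qr + qc * nr);
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
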