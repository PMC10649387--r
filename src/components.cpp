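#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of equal integer value in a matrix.
// Cells that are NA are background (label 0). Connectivity 4 or 8.
// Two neighbouring cells belong to the same component iff their values
// are equal. Labels are positive integers in scan order of discovery.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(IntegerMatrix x, int connectivity = 8) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;

  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (lab(r0, c0) != 0 || x(r0, c0) == NA_INTEGER) continue;
      const int v = x(r0, c0);
      ++next;
      lab(r0, c0) = next;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int r = idx % nr, c = idx / nr;
        for (int k = 0; k < nn; ++k) {
          const int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (lab(rr, cc) != 0) continue;
          if (x(rr, cc) == NA_INTEGER || x(rr, cc) != v) continue;
          lab(rr, cc) = next;
          stack.push_back(rr + cc * nr);
        }
      }
    }
  }
  return lab;
}
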