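#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of equal values in an integer matrix.
// NA cells are background (label 0). connectivity is 4 or 8.
// Returns an integer matrix of component labels (1-based, row-major discovery
// order) with 0 for background.
// [[Rcpp::export]]
IntegerMatrix cc_label(IntegerMatrix m, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);

  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  const int nd = connectivity;

  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) != 0 || m(i, j) == NA_INTEGER) continue;
      const int v = m(i, j);
      lab(i, j) = ++next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nd; ++k) {
          const int ni = ci + dr[k], nj = cj + dc[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (lab(ni, nj) != 0) continue;
          if (m(ni, nj) == NA_INTEGER || m(ni, nj) != v) continue;
          lab(ni, nj) = next;
          stack.push_back(ni + nj * nr);
        }
      }
    }
  }
  return lab;
}
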