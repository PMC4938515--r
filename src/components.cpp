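#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected-component labelling of a class raster. Pixels with NA code are
// background. Two adjacent pixels join a component iff their codes are equal.
// connectivity: 4 (edge neighbours) or 8 (edge + diagonal).
// Labels are assigned in row-major order of each component's first pixel,
// starting at 1; background stays 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix code, int connectivity) {
  const int nr = code.nrow(), nc = code.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);

  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;

  int next = 0;
  std::queue<std::pair<int, int> > q;
  // row-major scan so that first-pixel order matches the documented contract
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (lab(i, j) != 0 || code(i, j) == NA_INTEGER) continue;
      const int cls = code(i, j);
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nd; ++k) {
          const int r = p.first + dr[k], c = p.second + dc[k];
          if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
          if (lab(r, c) != 0 || code(r, c) != cls) continue;
          lab(r, c) = next;
          q.push(std::make_pair(r, c));
        }
      }
    }
  }
  return lab;
}
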