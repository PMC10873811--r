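#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 0/1 mask by flood fill.
// connectivity: 4 or 8. Labels are 1..n in scan order; background stays 0.

// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(IntegerMatrix img, int connectivity) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;

  std::vector<int> stack;
  int cur = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (img(r, c) != 0 && lab(r, c) == 0) {
        ++cur;
        lab(r, c) = cur;
        stack.push_back(r + c * nr);
        while (!stack.empty()) {
          int idx = stack.back();
          stack.pop_back();
          int rr = idx % nr, cc = idx / nr;
          for (int k = 0; k < nd; ++k) {
            int r2 = rr + dr[k], c2 = cc + dc[k];
            if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc &&
                img(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = cur;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
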