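#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact unit-cost Levenshtein distance on integer code vectors,
// rolling-row DP.

// [[Rcpp::export]]
int lev_full_cpp(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int c = prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
      const int d = std::min(prev[j], cur[j - 1]) + 1;
      cur[j] = std::min(c, d);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Banded (Ukkonen) variant: exact while the distance is <= cap, otherwise
// returns cap + 1. Used where only distances up to a cutoff matter.

// [[Rcpp::export]]
int lev_capped_cpp(IntegerVector a, IntegerVector b, int cap) {
  const int n = a.size(), m = b.size();
  if (std::abs(n - m) > cap) return cap + 1;
  const int INF = cap + 1;
  std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
  for (int j = 0; j <= std::min(m, cap); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(1, i - cap), jhi = std::min(m, i + cap);
    std::fill(cur.begin(), cur.end(), INF);
    if (i <= cap) cur[0] = i;
    const int ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const int c = prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
      int v = std::min(c, std::min(prev[j], cur[j - 1]) + 1);
      if (v > INF) v = INF;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  return std::min(prev[m], INF);
}

// Symmetric pairwise capped-distance matrix over a list of code vectors.

// [[Rcpp::export]]
IntegerMatrix lev_pairwise_cpp(List texts, int cap) {
  const int n = texts.size();
  IntegerMatrix d(n, n);
  std::vector<IntegerVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = texts[i];
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int x = lev_capped_cpp(v[i], v[j], cap);
      d(i, j) = x;
      d(j, i) = x;
    }
  }
  return d;
}
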