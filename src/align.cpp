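#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment of a character sequence against a
// profile (a set of already-aligned rows), maximising the summed column score
// under an affine gap model in which the FIRST gap symbol of a run costs
// gap_open and every subsequent symbol costs gap_extend.
//
// prof: K x L integer matrix of alphabet codes (1-based), 0 = gap.
// seq:  length-M integer vector of alphabet codes (1-based, no gaps).
// sim:  A x A substitution score matrix over the alphabet.
//
// The score of aligning character c against profile column j is the mean of
// sim[c, q] over the non-gap entries q of the column; gap placement against a
// column (or a new all-gap column inserted into the profile) is charged the
// affine gap cost once, not per row.
//
// States: 0 = M (column consumed against character), 1 = X (profile column
// against gap in seq), 2 = Y (seq character against gap column in profile).
// Ties are broken M, then X (gap in the incoming sequence, i.e. the second
// operand of a pairwise alignment), then Y.

static inline int best3(double m, double x, double y, double &out) {
  // priority order M > X > Y on exact ties
  if (m >= x && m >= y) { out = m; return 0; }
  if (x >= y)           { out = x; return 1; }
  out = y; return 2;
}

// band < 0 computes the full DP (exact optimum); band >= 0 restricts column
// j to within `band` of the main diagonal scaled to the two lengths, the
// usual banded-DP speedup for near-identical sequences. The band always
// contains the corner-to-corner path, so a valid (if possibly suboptimal
// when the true path leaves the band) alignment is always produced.

// [[Rcpp::export]]
List gotoh_profile_align(IntegerMatrix prof, IntegerVector seq,
                         NumericMatrix sim, double gap_open,
                         double gap_extend, int band = -1) {
  const int K = prof.nrow();
  const int L = prof.ncol();
  const int M = seq.size();
  const int A = sim.nrow();
  const double NEG = -1e30;

  // pre-computed score of each alphabet code against each profile column
  std::vector<double> cs((size_t)A * L, 0.0);
  for (int j = 0; j < L; ++j) {
    int n = 0;
    for (int r = 0; r < K; ++r) {
      int q = prof(r, j);
      if (q > 0) {
        ++n;
        for (int a = 0; a < A; ++a) cs[(size_t)a * L + j] += sim(a, q - 1);
      }
    }
    if (n > 0)
      for (int a = 0; a < A; ++a) cs[(size_t)a * L + j] /= n;
  }

  const size_t W = (size_t)(M + 1);
  std::vector<double> SM((L + 1) * W, NEG), SX((L + 1) * W, NEG),
      SY((L + 1) * W, NEG);
  std::vector<unsigned char> PM((L + 1) * W), PX((L + 1) * W), PY((L + 1) * W);
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };

  SM[at(0, 0)] = 0.0;
  for (int i = 1; i <= L; ++i) {
    SX[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    PX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= M; ++j) {
    SY[at(0, j)] = gap_open + (j - 1) * gap_extend;
    PY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= L; ++i) {
    int jlo = 1, jhi = M;
    if (band >= 0 && L > 0) {
      const int center = (int)std::lround((double)i * M / L);
      jlo = std::max(1, center - band);
      jhi = std::min(M, center + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double sc = cs[(size_t)(seq[j - 1] - 1) * L + (i - 1)];
      double b;
      int p = best3(SM[at(i - 1, j - 1)], SX[at(i - 1, j - 1)],
                    SY[at(i - 1, j - 1)], b);
      SM[at(i, j)] = b + sc;
      PM[at(i, j)] = (unsigned char)p;

      p = best3(SM[at(i - 1, j)] + gap_open, SX[at(i - 1, j)] + gap_extend,
                SY[at(i - 1, j)] + gap_open, b);
      SX[at(i, j)] = b;
      PX[at(i, j)] = (unsigned char)p;

      p = best3(SM[at(i, j - 1)] + gap_open, SX[at(i, j - 1)] + gap_open,
                SY[at(i, j - 1)] + gap_extend, b);
      // note candidate order above is (M, X, Y) positions: M, X, Y
      SY[at(i, j)] = b;
      PY[at(i, j)] = (unsigned char)p;
    }
  }

  double score;
  int state = best3(SM[at(L, M)], SX[at(L, M)], SY[at(L, M)], score);
  if (L == 0 && M == 0) { state = 0; score = 0.0; }

  std::vector<int> outProf, outSeq;
  int i = L, j = M;
  while (i > 0 || j > 0) {
    if (state == 0) {
      outProf.push_back(i); outSeq.push_back(j);
      state = PM[at(i, j)]; --i; --j;
    } else if (state == 1) {
      outProf.push_back(i); outSeq.push_back(0);
      state = PX[at(i, j)]; --i;
    } else {
      outProf.push_back(0); outSeq.push_back(j);
      state = PY[at(i, j)]; --j;
    }
  }
  std::reverse(outProf.begin(), outProf.end());
  std::reverse(outSeq.begin(), outSeq.end());

  return List::create(_["score"] = score,
                      _["prof_idx"] = wrap(outProf),
                      _["seq_idx"] = wrap(outSeq));
}
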