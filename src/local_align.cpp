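#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman with affine gaps (Gotoh three-state recursion).
// Gap of length L costs gap_open + (L-1)*gap_extend, i.e. the opening
// penalty is charged once per gap event. With the default scoring
// (match +1, mismatch -1, open -1, extend 0) the optimal score equals
// matches - mismatches - (gap events), the hit-score model used for
// gold-standard presence checks.
//
// Tie-break: the end cell with the maximal score and smallest (i, j) in
// row-major order wins; traceback prefers diagonal, then a gap in the
// target, then a gap in the query. This makes reported intervals
// deterministic; the score itself is tie-free.

static const int8_t TB_STOP = 0, TB_DIAG = 1, TB_UP = 2, TB_LEFT = 3;

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string query, std::string target,
              double match, double mismatch,
              double gap_open, double gap_extend) {
  const int n = (int) query.size();
  const int m = (int) target.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double) (n + 1) * (double) (m + 1) > 3e7)
    stop("sequences too long for exhaustive local alignment (DP matrix > 3e7 cells)");
  const double NEG = -1e18;

  // (n+1) x (m+1) matrices, row-major
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((size_t)(n + 1) * (m + 1), NEG); // query char vs gap (gap in target)
  std::vector<double> Iy((size_t)(n + 1) * (m + 1), NEG); // target char vs gap (gap in query)
  std::vector<int8_t> tbH((size_t)(n + 1) * (m + 1), TB_STOP);
  std::vector<int8_t> tbIx((size_t)(n + 1) * (m + 1), 0); // 1 = opened from H, 0 = extended
  std::vector<int8_t> tbIy((size_t)(n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  const size_t M = (size_t) m + 1;

  for (int i = 1; i <= n; ++i) {
    const char qa = query[(size_t) i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t k = (size_t) i * M + j;
      // gap in target (consume query char)
      double open_x = H[k - M] + gap_open;
      double ext_x  = Ix[k - M] + gap_extend;
      if (open_x >= ext_x) { Ix[k] = open_x; tbIx[k] = 1; }
      else                 { Ix[k] = ext_x;  tbIx[k] = 0; }
      // gap in query (consume target char)
      double open_y = H[k - 1] + gap_open;
      double ext_y  = Iy[k - 1] + gap_extend;
      if (open_y >= ext_y) { Iy[k] = open_y; tbIy[k] = 1; }
      else                 { Iy[k] = ext_y;  tbIy[k] = 0; }

      const double s = (qa == target[(size_t) j - 1]) ? match : mismatch;
      const double diag = H[k - M - 1] + s;
      double h = 0.0; int8_t tb = TB_STOP;
      if (diag > h)  { h = diag;  tb = TB_DIAG; }
      if (Ix[k] > h) { h = Ix[k]; tb = TB_UP; }
      if (Iy[k] > h) { h = Iy[k]; tb = TB_LEFT; }
      H[k] = h; tbH[k] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj)
  long matches = 0, mismatches = 0;
  long q_gap_count = 0, t_gap_count = 0, q_gap_bases = 0, t_gap_bases = 0;
  int i = bi, j = bj;
  int q_end = bi, t_end = bj, q_start = bi + 1, t_start = bj + 1;
  std::string qa_str, ta_str;
  int state = 0; // 0 = H, 1 = Ix, 2 = Iy
  while (i > 0 && j > 0) {
    const size_t k = (size_t) i * M + j;
    if (state == 0) {
      const int8_t tb = tbH[k];
      if (tb == TB_STOP) break;
      if (tb == TB_DIAG) {
        if (query[(size_t) i - 1] == target[(size_t) j - 1]) ++matches; else ++mismatches;
        qa_str.push_back(query[(size_t) i - 1]);
        ta_str.push_back(target[(size_t) j - 1]);
        q_start = i; t_start = j;
        --i; --j;
      } else if (tb == TB_UP) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // gap in target, consume query char
      qa_str.push_back(query[(size_t) i - 1]);
      ta_str.push_back('-');
      ++t_gap_bases;
      q_start = i;
      const int8_t opened = tbIx[k];
      --i;
      if (opened) { ++t_gap_count; state = 0; }
    } else { // gap in query, consume target char
      qa_str.push_back('-');
      ta_str.push_back(target[(size_t) j - 1]);
      ++q_gap_bases;
      t_start = j;
      const int8_t opened = tbIy[k];
      --j;
      if (opened) { ++q_gap_count; state = 0; }
    }
  }
  std::reverse(qa_str.begin(), qa_str.end());
  std::reverse(ta_str.begin(), ta_str.end());
  if (best <= 0.0) { // empty alignment
    q_start = q_end = t_start = t_end = 0;
    qa_str.clear(); ta_str.clear();
  }

  return List::create(
    _["score"] = best,
    _["matches"] = (double) matches,
    _["mismatches"] = (double) mismatches,
    _["q_gap_count"] = (double) q_gap_count,
    _["t_gap_count"] = (double) t_gap_count,
    _["q_gap_bases"] = (double) q_gap_bases,
    _["t_gap_bases"] = (double) t_gap_bases,
    _["q_start"] = q_start, _["q_end"] = q_end,
    _["t_start"] = t_start, _["t_end"] = t_end,
    _["q_aligned"] = qa_str, _["t_aligned"] = ta_str);
}
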