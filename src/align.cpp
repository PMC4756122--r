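#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>

using namespace Rcpp;

// Affine-gap pairwise alignment kernels shared by the search, clustering and
// star-alignment layers. Scoring convention: a gap of length L costs
// gap_open + L * gap_extend (both negative). Only A/C/G/T can match; any
// other symbol pair (including N vs N) scores as a mismatch.

static const int NEG = INT_MIN / 4;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline int sub_score(char a, char b, int match, int mismatch) {
  return (a == b && is_acgt(a)) ? match : mismatch;
}

// Local (Smith-Waterman, Gotoh affine) alignment of q vs s.
// band_lo/band_hi restrict computation to diagonals band_lo <= j - i <= band_hi
// (1-based DP indices; diagonal of cell (i,j) is j - i). Pass band_lo <= -m and
// band_hi >= n for an exact, unbanded alignment.
// Returns best score, 0-based half-open coordinates on both sequences,
// match count and aligned column count of the traceback alignment.
// [[Rcpp::export]]
List align_local_cpp(std::string q, std::string s,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int band_lo, int band_hi) {
  const int m = (int) q.size(), n = (int) s.size();
  std::vector<int> H((m + 1) * (n + 1), 0),
                   E((m + 1) * (n + 1), NEG),
                   F((m + 1) * (n + 1), NEG);
  const int W = n + 1;
  int best = 0, bi = 0, bj = 0;
  const int ge = gap_extend, go = gap_open;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + band_lo), jhi = std::min(n, i + band_hi);
    for (int j = jlo; j <= jhi; ++j) {
      const int idx = i * W + j;
      int e = std::max(H[idx - 1] + go + ge,
                       E[idx - 1] == NEG ? NEG : E[idx - 1] + ge);
      int f = std::max(H[idx - W] + go + ge,
                       F[idx - W] == NEG ? NEG : F[idx - W] + ge);
      E[idx] = e;
      F[idx] = f;
      int d = H[idx - W - 1] + sub_score(q[i - 1], s[j - 1], match, mismatch);
      int h = d;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int n_match = 0, n_col = 0;
  int i = bi, j = bj;
  if (best > 0) {
    int state = 0; // 0 = H, 1 = E (gap in query, consume s), 2 = F (consume q)
    while (i > 0 && j > 0) {
      const int idx = i * W + j;
      if (state == 0) {
        if (H[idx] == 0) break;
        int d = H[idx - W - 1] + sub_score(q[i - 1], s[j - 1], match, mismatch);
        if (H[idx] == d) {
          ++n_col;
          if (q[i - 1] == s[j - 1] && is_acgt(q[i - 1])) ++n_match;
          --i; --j;
        } else if (H[idx] == E[idx]) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        const int idx2 = i * W + j;
        ++n_col;
        bool from_e = (E[idx2 - 1] != NEG && E[idx2] == E[idx2 - 1] + ge);
        --j;
        if (!from_e) state = 0;
      } else {
        const int idx2 = i * W + j;
        ++n_col;
        bool from_f = (F[idx2 - W] != NEG && F[idx2] == F[idx2 - W] + ge);
        --i;
        if (!from_f) state = 0;
      }
    }
  }
  return List::create(
    _["score"] = best,
    _["q_start"] = (best > 0) ? i : 0,
    _["q_end"] = (best > 0) ? bi : 0,
    _["s_start"] = (best > 0) ? j : 0,
    _["s_end"] = (best > 0) ? bj : 0,
    _["matches"] = n_match,
    _["columns"] = n_col);
}

// Ends-free ("overlap") global alignment: terminal gaps on either sequence
// are free; interior gaps are affine. Returns the full-length gapped strings
// (unaligned overhangs stacked as gap-vs-residue columns), the aligned core
// coordinates, and the match count over core columns.
// [[Rcpp::export]]
List align_overlap_cpp(std::string q, std::string s,
                       int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int) q.size(), n = (int) s.size();
  const int W = n + 1;
  std::vector<int> H((m + 1) * (n + 1), 0),
                   E((m + 1) * (n + 1), NEG),
                   F((m + 1) * (n + 1), NEG);
  const int ge = gap_extend, go = gap_open;
  // H[0][j] = H[i][0] = 0: leading end gaps free
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      int e = std::max(H[idx - 1] + go + ge,
                       E[idx - 1] == NEG ? NEG : E[idx - 1] + ge);
      int f = std::max(H[idx - W] + go + ge,
                       F[idx - W] == NEG ? NEG : F[idx - W] + ge);
      E[idx] = e;
      F[idx] = f;
      int d = H[idx - W - 1] + sub_score(q[i - 1], s[j - 1], match, mismatch);
      int h = d;
      if (e > h) h = e;
      if (f > h) h = f;
      H[idx] = h;
    }
  }
  // best over last row and last column (trailing end gaps free)
  int best = NEG, bi = m, bj = n;
  for (int j = 0; j <= n; ++j)
    if (H[m * W + j] >= best) { best = H[m * W + j]; bi = m; bj = j; }
  for (int i = 0; i <= m; ++i)
    if (H[i * W + n] > best) { best = H[i * W + n]; bi = i; bj = n; }

  std::string qa, sa; // core alignment, built reversed
  int n_match = 0;
  int i = bi, j = bj;
  int state = 0;
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      int d = H[idx - W - 1] + sub_score(q[i - 1], s[j - 1], match, mismatch);
      if (H[idx] == d) {
        qa.push_back(q[i - 1]);
        sa.push_back(s[j - 1]);
        if (q[i - 1] == s[j - 1] && is_acgt(q[i - 1])) ++n_match;
        --i; --j;
      } else if (H[idx] == E[idx]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      qa.push_back('-');
      sa.push_back(s[j - 1]);
      bool from_e = (E[idx - 1] != NEG && E[idx] == E[idx - 1] + ge);
      --j;
      if (!from_e) state = 0;
    } else {
      qa.push_back(q[i - 1]);
      sa.push_back('-');
      bool from_f = (F[idx - W] != NEG && F[idx] == F[idx - W] + ge);
      --i;
      if (!from_f) state = 0;
    }
  }
  const int core_q_start = i, core_s_start = j;
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  // stack unaligned overhangs: leading q, leading s, core, trailing q, trailing s
  std::string q_full, s_full;
  q_full.append(q.substr(0, core_q_start));
  s_full.append(std::string(core_q_start, '-'));
  q_full.append(std::string(core_s_start, '-'));
  s_full.append(s.substr(0, core_s_start));
  q_full += qa;
  s_full += sa;
  q_full.append(q.substr(bi));
  s_full.append(std::string(m - bi, '-'));
  q_full.append(std::string(n - bj, '-'));
  s_full.append(s.substr(bj));
  return List::create(
    _["score"] = best,
    _["q_aln"] = q_full,
    _["s_aln"] = s_full,
    _["q_core_start"] = core_q_start,
    _["q_core_end"] = bi,
    _["s_core_start"] = core_s_start,
    _["s_core_end"] = bj,
    _["matches"] = n_match);
}
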