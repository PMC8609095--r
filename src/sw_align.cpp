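#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Affine-gap Smith-Waterman with iterative residue masking.
//
// A gap of length L costs gap_open + L * gap_extend (blastp convention).
// After each reported alignment every residue inside its query and subject
// spans is masked, and the DP is re-run, so reported segments are mutually
// non-overlapping on both sequences.

static const int NEG = INT_MIN / 4;

struct Hit {
  int score, qs, qe, ss, se;           // 1-based inclusive spans
  std::vector<int> qpos, spos;         // per-column residue position, 0 = gap
};

static bool run_dp(const std::vector<int> &q, const std::vector<int> &s,
                   const IntegerMatrix &sub, int open, int ext,
                   const std::vector<char> &qmask, const std::vector<char> &smask,
                   int min_score, Hit &hit) {
  const int m = q.size(), n = s.size();
  const int oe = open + ext;
  std::vector<int> M((m + 1) * (n + 1), 0), Ix((m + 1) * (n + 1), NEG),
      Iy((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int ix = NEG, iy = NEG, mm = NEG;
      if (!qmask[i - 1]) {
        int a = M[at(i - 1, j)] - oe, b = Ix[at(i - 1, j)] - ext;
        ix = a > b ? a : b;
      }
      if (!smask[j - 1]) {
        int a = M[at(i, j - 1)] - oe, b = Iy[at(i, j - 1)] - ext;
        iy = a > b ? a : b;
      }
      if (!qmask[i - 1] && !smask[j - 1]) {
        int d = M[at(i - 1, j - 1)];
        if (Ix[at(i - 1, j - 1)] > d) d = Ix[at(i - 1, j - 1)];
        if (Iy[at(i - 1, j - 1)] > d) d = Iy[at(i - 1, j - 1)];
        if (d < 0) d = 0;
        mm = d + sub(q[i - 1], s[j - 1]);
        if (mm < 0) mm = 0;
      } else {
        mm = 0;
      }
      M[at(i, j)] = mm;
      Ix[at(i, j)] = ix;
      Iy[at(i, j)] = iy;
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
  }
  if (best < min_score || best <= 0) return false;

  // traceback from (bi, bj) in state M
  std::vector<int> qpos, spos;
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  while (true) {
    if (state == 0) {
      qpos.push_back(i); spos.push_back(j);
      int d = M[at(i - 1, j - 1)], x = Ix[at(i - 1, j - 1)], y = Iy[at(i - 1, j - 1)];
      int prev = d; if (x > prev) prev = x; if (y > prev) prev = y;
      if (prev <= 0) { --i; --j; break; }
      if (prev == d) state = 0; else if (prev == x) state = 1; else state = 2;
      --i; --j;
    } else if (state == 1) {  // gap in subject, consumes query residue i
      qpos.push_back(i); spos.push_back(0);
      if (Ix[at(i, j)] == M[at(i - 1, j)] - oe) state = 0; else state = 1;
      --i;
    } else {  // gap in query, consumes subject residue j
      qpos.push_back(0); spos.push_back(j);
      if (Iy[at(i, j)] == M[at(i, j - 1)] - oe) state = 0; else state = 2;
      --j;
    }
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(spos.begin(), spos.end());
  hit.score = best;
  hit.qs = i + 1; hit.qe = bi; hit.ss = j + 1; hit.se = bj;
  hit.qpos = qpos; hit.spos = spos;
  return true;
}

// [[Rcpp::export]]
List sw_align_masked(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                     int gap_open, int gap_extend, int max_segments,
                     int min_score) {
  std::vector<int> qv(q.begin(), q.end()), sv(s.begin(), s.end());
  std::vector<char> qmask(qv.size(), 0), smask(sv.size(), 0);
  List out;
  for (int k = 0; k < max_segments; ++k) {
    Hit hit;
    if (!run_dp(qv, sv, sub, gap_open, gap_extend, qmask, smask, min_score, hit))
      break;
    out.push_back(List::create(
        _["raw_score"] = hit.score, _["q_start"] = hit.qs, _["q_end"] = hit.qe,
        _["s_start"] = hit.ss, _["s_end"] = hit.se,
        _["q_pos"] = IntegerVector(hit.qpos.begin(), hit.qpos.end()),
        _["s_pos"] = IntegerVector(hit.spos.begin(), hit.spos.end())));
    for (int i = hit.qs - 1; i < hit.qe; ++i) qmask[i] = 1;
    for (int j = hit.ss - 1; j < hit.se; ++j) smask[j] = 1;
  }
  return out;
}
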