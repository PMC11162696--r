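#include <Rcpp.h>
#include <climits>
#include "rt_core.h"

using namespace Rcpp;

// Levenshtein distance; band > 0 restricts |i - j| <= band (Ukkonen cutoff)
// and returns band + 1 when the true distance exceeds the band.
// [[Rcpp::export]]
int rt_edit_distance(std::string a, std::string b, int band = -1) {
  int m = (int)a.size(), n = (int)b.size();
  if (band > 0 && std::abs(m - n) > band) return band + 1;
  const int BIG = INT_MAX / 4;
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j)
    prev[j] = (band > 0 && j > band) ? BIG : j;
  for (int i = 1; i <= m; ++i) {
    int lo = 1, hi = n;
    if (band > 0) { lo = std::max(1, i - band); hi = std::min(n, i + band); }
    std::fill(cur.begin(), cur.end(), BIG);
    if (lo == 1) cur[0] = (band > 0 && i > band) ? BIG : i;
    for (int j = lo; j <= hi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  int d = prev[n];
  if (band > 0 && d > band) return band + 1;
  return d;
}

// Locate where the END of `pattern` best aligns inside `text`, allowing the
// pattern PREFIX to be clipped for free (reads truncated at the transcript
// 5' end) while the text must be consumed from its first base.
//
// Score-based (match +1, mismatch/gap -2) rather than edit-distance-based:
// under free prefix clipping a distance formulation degenerates, because a
// chance match of the pattern's last base near the text start costs 0 while
// the true, long alignment accumulates error cost. Maximizing an
// alignment score makes long good alignments dominate short spurious ones.
//
// Returns the 1-based text position of the pattern end and an edit-like
// cost (error-cost units of the winning placement, (j - score) / 3).
// [[Rcpp::export]]
List rt_anchor_prefix(std::string pattern, std::string text) {
  const int MATCH = 1, MIS = -2, GAP = -2;
  int m = (int)pattern.size(), n = (int)text.size();
  if (m == 0 || n == 0) return List::create(_["end"] = 0, _["dist"] = 0);
  const int NEG = INT_MIN / 4;
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = GAP * j;  // text prefix must align
  for (int i = 1; i <= m; ++i) {
    cur[0] = 0;  // pattern prefix clipped for free
    for (int j = 1; j <= n; ++j) {
      int diag = prev[j - 1] + (pattern[i - 1] == text[j - 1] ? MATCH : MIS);
      int up = prev[j] + GAP;
      int left = cur[j - 1] + GAP;
      int v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < NEG) v = NEG;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  // ties prefer the largest text position (most text explained)
  int best_j = 1, best = prev[1];
  for (int j = 2; j <= n; ++j)
    if (prev[j] >= best) { best = prev[j]; best_j = j; }
  int dist = (best_j - best + 2) / 3;  // mismatch/gap each cost 3 vs a match
  if (dist < 0) dist = 0;
  return List::create(_["end"] = best_j, _["dist"] = dist);
}

// Mirror case: locate where the START of `pattern` best aligns inside `text`,
// allowing the pattern SUFFIX to be clipped (reads truncated at the 3' end)
// while the text must be consumed to its last base.
// [[Rcpp::export]]
List rt_anchor_suffix(std::string pattern, std::string text) {
  std::reverse(pattern.begin(), pattern.end());
  std::reverse(text.begin(), text.end());
  List res = rt_anchor_prefix(pattern, text);
  int end_rev = as<int>(res["end"]);
  int n = (int)text.size();
  return List::create(_["start"] = n - end_rev + 1, _["dist"] = res["dist"]);
}

// i.i.d. per-base error injection (substitution, insertion, deletion) using
// R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector rt_mutate(CharacterVector seqs, double p_sub, double p_ins,
                          double p_del) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r;
    r.reserve(s.size() + 16);
    for (char c : s) {
      double u = unif_rand();
      if (u < p_del) {
        // base dropped
      } else if (u < p_del + p_sub) {
        int cc = rt::base_code(c);
        int b = (int)(unif_rand() * 3.0);
        if (b > 2) b = 2;
        if (cc >= 0) r.push_back(bases[(cc + 1 + b) % 4]);
        else r.push_back(bases[b]);
      } else {
        r.push_back(c);
      }
      if (unif_rand() < p_ins) {
        int b = (int)(unif_rand() * 4.0);
        if (b > 3) b = 3;
        r.push_back(bases[b]);
      }
    }
    out[i] = r;
  }
  return out;
}
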