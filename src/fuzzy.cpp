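#include <Rcpp.h>
using namespace Rcpp;

// Semi-global (substring) Levenshtein matcher. The pattern must align to a
// contiguous substring of the text; the substring's start and end are free.
// Inputs are expected to be case-folded already by the R wrapper.

// For every end position in `text`, the minimal edit distance of `pattern`
// to a substring ending there, together with the start attaining it.
// Ties on distance prefer the larger start (shorter span).
// Returns an integer matrix with columns start, end, dist (1-based,
// inclusive) for positions with dist <= k and a non-empty span.
// [[Rcpp::export]]
IntegerMatrix fuzzy_candidates_cpp(std::string pattern, std::string text, int k) {
  const int m = pattern.size(), n = text.size();
  if (m == 0 || n == 0) return IntegerMatrix(0, 3);

  std::vector<int> prev_d(n + 1), cur_d(n + 1);
  std::vector<int> prev_s(n + 1), cur_s(n + 1);
  for (int j = 0; j <= n; ++j) { prev_d[j] = 0; prev_s[j] = j + 1; }

  for (int i = 1; i <= m; ++i) {
    cur_d[0] = i; cur_s[0] = 1;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int sub_d = prev_d[j - 1] + (pc != text[j - 1] ? 1 : 0);
      int sub_s = prev_s[j - 1];
      int del_d = prev_d[j] + 1;  // drop a pattern char
      int del_s = prev_s[j];
      int ins_d = cur_d[j - 1] + 1;  // absorb an extra text char
      int ins_s = cur_s[j - 1];
      int d = sub_d, s = sub_s;
      if (del_d < d || (del_d == d && del_s > s)) { d = del_d; s = del_s; }
      if (ins_d < d || (ins_d == d && ins_s > s)) { d = ins_d; s = ins_s; }
      cur_d[j] = d; cur_s[j] = s;
    }
    std::swap(prev_d, cur_d);
    std::swap(prev_s, cur_s);
  }

  std::vector<int> starts, ends, dists;
  for (int j = 1; j <= n; ++j) {
    if (prev_d[j] <= k && prev_s[j] <= j) {
      starts.push_back(prev_s[j]);
      ends.push_back(j);
      dists.push_back(prev_d[j]);
    }
  }
  IntegerMatrix out(starts.size(), 3);
  for (size_t r = 0; r < starts.size(); ++r) {
    out(r, 0) = starts[r]; out(r, 1) = ends[r]; out(r, 2) = dists[r];
  }
  colnames(out) = CharacterVector::create("start", "end", "dist");
  return out;
}

// Minimal edit distance of `pattern` to any substring of `text`.
// [[Rcpp::export]]
int min_partial_dist_cpp(std::string pattern, std::string text) {
  const int m = pattern.size(), n = text.size();
  if (m == 0) return 0;
  if (n == 0) return m;
  std::vector<int> prev(n + 1, 0), cur(n + 1);
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int d = prev[j - 1] + (pc != text[j - 1] ? 1 : 0);
      if (prev[j] + 1 < d) d = prev[j] + 1;
      if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  int best = m;
  for (int j = 1; j <= n; ++j) if (prev[j] < best) best = prev[j];
  return best;
}
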