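#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Unit-cost edit distance between two symbol sequences.
// Sequences arrive as std::vector<std::string> so multi-character phoneme
// symbols are supported; the hot path (one-symbol-per-character strings)
// goes through lev_dist_matrix_cpp below.
static int lev_core(const std::vector<std::string>& a,
                    const std::vector<std::string>& b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int) m;
  if (m == 0) return (int) n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int) j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int) i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static int lev_str(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int) m;
  if (m == 0) return (int) n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int) j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int) i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int lev_seq_cpp(std::vector<std::string> a, std::vector<std::string> b) {
  return lev_core(a, b);
}

// Distance from every target string to every lexicon string
// (one character = one symbol).
// [[Rcpp::export]]
IntegerMatrix lev_dist_matrix_cpp(CharacterVector targets,
                                  CharacterVector lexicon) {
  const int n = targets.size(), m = lexicon.size();
  std::vector<std::string> tg(n), lx(m);
  for (int i = 0; i < n; ++i) tg[i] = as<std::string>(targets[i]);
  for (int j = 0; j < m; ++j) lx[j] = as<std::string>(lexicon[j]);
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) out(i, j) = lev_str(tg[i], lx[j]);
  }
  return out;
}

// Hamming distance 1 among equal-length strings (Coltheart's N inner loop).
// [[Rcpp::export]]
IntegerVector coltheart_counts_cpp(CharacterVector targets,
                                   CharacterVector lexicon,
                                   bool das_mode) {
  const int n = targets.size(), m = lexicon.size();
  std::vector<std::string> tg(n), lx(m);
  for (int i = 0; i < n; ++i) tg[i] = as<std::string>(targets[i]);
  for (int j = 0; j < m; ++j) lx[j] = as<std::string>(lexicon[j]);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    for (int j = 0; j < m; ++j) {
      if (tg[i] == lx[j]) continue;  // the target never counts toward N
      if (das_mode) {
        size_t la = tg[i].size(), lb = lx[j].size();
        size_t d = la > lb ? la - lb : lb - la;
        if (d > 1) continue;
        if (lev_str(tg[i], lx[j]) == 1) ++cnt;
      } else {
        if (tg[i].size() != lx[j].size()) continue;
        int h = 0;
        for (size_t p = 0; p < tg[i].size() && h <= 1; ++p)
          if (tg[i][p] != lx[j][p]) ++h;
        if (h == 1) ++cnt;
      }
    }
    out[i] = cnt;
  }
  return out;
}
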