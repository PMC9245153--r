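#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// A small regression random forest: bootstrap bagging over CART-style
// variance-reduction trees with a random feature subset (mtry) at every
// split, out-of-bag predictions, and OOB permutation importance.
// Uses R's RNG so results are reproducible via set.seed() on the R side.

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> value;  // node mean (prediction at leaves)
};

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static double predict_one(const Tree& tr, const double* x, int nrow, int row) {
  int node = 0;
  while (tr.feat[node] >= 0) {
    double v = x[(size_t) tr.feat[node] * nrow + row];
    node = (v <= tr.thr[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.value[node];
}

// Grow one node (recursively) over idx[lo, hi).
static int grow(Tree& tr, const NumericMatrix& X, const NumericVector& y,
                std::vector<int>& idx, int lo, int hi,
                int mtry, int min_node, std::vector<int>& featpool) {
  const int n = hi - lo;
  double sum = 0.0;
  for (int i = lo; i < hi; ++i) sum += y[idx[i]];
  const double mean = sum / n;

  int node = (int) tr.feat.size();
  tr.feat.push_back(-1); tr.thr.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1);
  tr.value.push_back(mean);
  if (n <= min_node) return node;

  const int p = X.ncol();
  // partial Fisher-Yates: first mtry entries of featpool are the candidates
  for (int i = 0; i < mtry; ++i) {
    int j = i + rand_int(p - i);
    std::swap(featpool[i], featpool[j]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  std::vector<std::pair<double, double> > vals(n);  // (x, y)
  for (int f = 0; f < mtry; ++f) {
    const int j = featpool[f];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(idx[lo + i], j), y[idx[lo + i]]);
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;  // constant feature
    double lsum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;  // not a cut point
      const int nl = i + 1, nr = n - nl;
      const double rsum = sum - lsum;
      // SSE decrease up to a constant: nl*meanL^2 + nr*meanR^2 - n*mean^2
      double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = j;
        best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
      }
    }
  }
  if (best_feat < 0) return node;  // no informative split among candidates

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;  // numeric safety

  tr.feat[node] = best_feat;
  tr.thr[node] = best_thr;
  int l = grow(tr, X, y, idx, lo, mid, mtry, min_node, featpool);
  int r = grow(tr, X, y, idx, mid, hi, mtry, min_node, featpool);
  tr.left[node] = l;
  tr.right[node] = r;
  return node;
}

static List tree_to_list(const Tree& tr) {
  return List::create(_["feat"] = wrap(tr.feat), _["thr"] = wrap(tr.thr),
                      _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
                      _["value"] = wrap(tr.value));
}

static Tree tree_from_list(const List& l) {
  Tree tr;
  tr.feat = as<std::vector<int> >(l["feat"]);
  tr.thr = as<std::vector<double> >(l["thr"]);
  tr.left = as<std::vector<int> >(l["left"]);
  tr.right = as<std::vector<int> >(l["right"]);
  tr.value = as<std::vector<double> >(l["value"]);
  return tr;
}

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntrees, int mtry,
                int min_node, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_cnt(n, 0);
  NumericVector imp(p, 0.0);
  List trees(ntrees);
  std::vector<int> featpool(p);
  std::vector<int> idx;
  std::vector<char> inbag(n);
  std::vector<int> oob;
  std::vector<double> xoob;  // OOB rows, column-major, for importance

  for (int t = 0; t < ntrees; ++t) {
    for (int j = 0; j < p; ++j) featpool[j] = j;
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      int s = rand_int(n);
      idx.push_back(s);
      inbag[s] = 1;
    }
    Tree tr;
    grow(tr, X, y, idx, 0, n, mtry, min_node, featpool);
    trees[t] = tree_to_list(tr);

    oob.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    const int no = (int) oob.size();
    if (no == 0) continue;

    xoob.assign((size_t) no * p, 0.0);
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < no; ++i) xoob[(size_t) j * no + i] = X(oob[i], j);

    double mse0 = 0.0;
    for (int i = 0; i < no; ++i) {
      double pred = predict_one(tr, xoob.data(), no, i);
      oob_sum[oob[i]] += pred;
      oob_cnt[oob[i]] += 1;
      double e = y[oob[i]] - pred;
      mse0 += e * e;
    }
    mse0 /= no;

    if (importance) {
      std::vector<double> col(no), saved(no);
      for (int j = 0; j < p; ++j) {
        double* cj = xoob.data() + (size_t) j * no;
        std::copy(cj, cj + no, saved.begin());
        std::copy(cj, cj + no, col.begin());
        for (int i = no - 1; i > 0; --i)
          std::swap(col[i], col[rand_int(i + 1)]);
        std::copy(col.begin(), col.end(), cj);
        double msej = 0.0;
        for (int i = 0; i < no; ++i) {
          double e = y[oob[i]] - predict_one(tr, xoob.data(), no, i);
          msej += e * e;
        }
        msej /= no;
        imp[j] += msej - mse0;
        std::copy(saved.begin(), saved.end(), cj);
      }
    }
  }

  NumericVector oob_pred(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) oob_pred[i] = oob_sum[i] / oob_cnt[i];
  for (int j = 0; j < p; ++j) imp[j] /= ntrees;

  return List::create(_["trees"] = trees, _["oob_pred"] = oob_pred,
                      _["oob_count"] = oob_cnt, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), nt = trees.size();
  std::vector<double> xs((size_t) n * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) xs[(size_t) j * n + i] = X(i, j);
  NumericVector out(n, 0.0);
  for (int t = 0; t < nt; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_one(tr, xs.data(), n, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
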