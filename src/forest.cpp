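#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Small classification random forest (binary labels 0/1) with Gini splits,
// bootstrap resampling, per-node feature subsampling and mean-decrease-in-
// impurity importance. Self-contained xorshift RNG keeps fits reproducible
// across platforms for a given seed.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

struct Tree {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, max_depth, min_split, min_leaf;
  Rng& rng;
  Tree tree;
  std::vector<double>& importance;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int max_depth_, int min_split_, int min_leaf_, Rng& rng_,
          std::vector<double>& imp)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_),
        min_split(min_split_), min_leaf(min_leaf_), rng(rng_),
        importance(imp) {}

  static double gini(double n1, double n) {
    if (n <= 0) return 0.0;
    double p = n1 / n;
    return 2.0 * p * (1.0 - p);
  }

  int build(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    double n1 = 0;
    for (int i : idx) n1 += y[i];
    int node = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.value.push_back(n > 0 ? n1 / n : 0.5);
    if (depth >= max_depth || n < min_split || n1 == 0 || n1 == n)
      return node;

    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    // partial Fisher-Yates for mtry features
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j)
      std::swap(feats[j], feats[j + rng.unif_int(p - j)]);

    double parent_imp = gini(n1, n);
    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int j = feats[jj];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], j), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      double left1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        left1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double child = (nl * gini(left1, nl) + nr * gini(n1 - left1, nr)) / n;
        double gain = parent_imp - child;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = j;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return node;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) li.push_back(i);
      else ri.push_back(i);
    }
    if ((int)li.size() < min_leaf || (int)ri.size() < min_leaf) return node;
    importance[best_feat] += (double)n * best_gain;
    tree.feature[node] = best_feat;
    tree.threshold[node] = best_thr;
    int l = build(li, depth + 1);
    tree.left[node] = l;
    int r = build(ri, depth + 1);
    tree.right[node] = r;
    return node;
  }
};

double predict_tree(const List& tr, const NumericMatrix& X, int row) {
  IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
  NumericVector threshold = tr["threshold"], value = tr["value"];
  int node = 0;
  while (feature[node] >= 0)
    node = X(row, feature[node]) <= threshold[node] ? left[node] : right[node];
  return value[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
            int max_depth, int min_split, int min_leaf, bool bootstrap,
            double seed) {
  int n = X.nrow(), p = X.ncol();
  Rng rng((uint64_t)seed);
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    Builder b(X, y, mtry, max_depth, min_split, min_leaf, rng, importance);
    b.build(idx, 0);
    trees[t] = List::create(
        _["feature"] = IntegerVector(b.tree.feature.begin(), b.tree.feature.end()),
        _["left"] = IntegerVector(b.tree.left.begin(), b.tree.left.end()),
        _["right"] = IntegerVector(b.tree.right.begin(), b.tree.right.end()),
        _["threshold"] = NumericVector(b.tree.threshold.begin(), b.tree.threshold.end()),
        _["value"] = NumericVector(b.tree.value.begin(), b.tree.value.end()));
  }
  double tot = 0.0;
  for (double v : importance) tot += v;
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = tot > 0 ? importance[j] / tot : 0.0;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tr, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
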