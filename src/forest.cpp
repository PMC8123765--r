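// CART regression trees and a bagged random forest. For 0/1 labels the
// variance split criterion coincides with Gini impurity, so the same tree
// grower serves both the random forest (on class labels, averaged into a
// probability) and gradient boosting (on pseudo-residuals).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
#include <cstdint>
using namespace Rcpp;

static inline std::uint64_t xs64(std::uint64_t &s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17;
  return s * 2685821657736338717ULL;
}
static inline int rand_below(std::uint64_t &s, int n) {
  return (int)(((xs64(s) >> 11) * (1.0 / 9007199254740992.0)) * n);
}

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;
};

static void grow_node(const NumericMatrix &X, const NumericVector &y,
                      std::vector<int> &idx, int lo, int hi, int depth,
                      int mtry, int min_split, int max_depth,
                      std::uint64_t &rng, TreeNodes &T,
                      std::vector<int> &feat_pool) {
  const int node = (int)T.feature.size();
  const int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int i = lo; i < hi; ++i) { sum += y[idx[i]]; sum2 += y[idx[i]] * y[idx[i]]; }
  const double mean = sum / n;
  const double sse = sum2 - sum * sum / n;
  T.feature.push_back(-1); T.threshold.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1); T.value.push_back(mean);
  if (n < min_split || sse <= 1e-12 ||
      (max_depth > 0 && depth >= max_depth)) return;

  // draw mtry candidate features without replacement (partial Fisher-Yates)
  const int p = (int)feat_pool.size();
  for (int i = 0; i < mtry; ++i) {
    int j = i + rand_below(rng, p - i);
    std::swap(feat_pool[i], feat_pool[j]);
  }
  double best_gain = 1e-12; int best_f = -1; double best_thr = 0.0;
  std::vector<std::pair<double, double> > vals(n);  // (x, y)
  for (int fi = 0; fi < mtry; ++fi) {
    const int f = feat_pool[fi];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(idx[lo + i], f), y[idx[lo + i]]);
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;
    double lsum = 0.0, lsum2 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += vals[i].second; lsum2 += vals[i].second * vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      const double rsum = sum - lsum, rsum2 = sum2 - lsum2;
      const double child_sse = (lsum2 - lsum * lsum / nl) +
                               (rsum2 - rsum * rsum / nr);
      const double gain = sse - child_sse;
      if (gain > best_gain) {
        best_gain = gain; best_f = f;
        best_thr = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
      }
    }
  }
  if (best_f < 0) return;
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;  // numeric degeneracy guard
  T.feature[node] = best_f; T.threshold[node] = best_thr;
  T.left[node] = (int)T.feature.size();
  grow_node(X, y, idx, lo, mid, depth + 1, mtry, min_split, max_depth,
            rng, T, feat_pool);
  T.right[node] = (int)T.feature.size();
  grow_node(X, y, idx, mid, hi, depth + 1, mtry, min_split, max_depth,
            rng, T, feat_pool);
}

static List tree_to_list(const TreeNodes &T) {
  return List::create(_["feature"] = wrap(T.feature),
                      _["threshold"] = wrap(T.threshold),
                      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
                      _["value"] = wrap(T.value));
}

static List grow_tree_impl(const NumericMatrix &X, const NumericVector &y,
                           const std::vector<int> &samples, int mtry,
                           int min_split, int max_depth, std::uint64_t &rng) {
  TreeNodes T;
  std::vector<int> idx(samples);
  std::vector<int> feat_pool(X.ncol());
  std::iota(feat_pool.begin(), feat_pool.end(), 0);
  if (mtry < 1) mtry = 1;
  if (mtry > X.ncol()) mtry = X.ncol();
  grow_node(X, y, idx, 0, (int)idx.size(), 0, mtry, min_split, max_depth,
            rng, T, feat_pool);
  return tree_to_list(T);
}

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector y, int mtry, int min_split,
                   int max_depth, int seed) {
  std::uint64_t rng = (std::uint64_t)seed * 6364136223846793005ULL + 99991ULL;
  for (int k = 0; k < 8; ++k) xs64(rng);
  std::vector<int> samples(X.nrow());
  std::iota(samples.begin(), samples.end(), 0);
  return grow_tree_impl(X, y, samples, mtry, min_split, max_depth, rng);
}

static void predict_tree(const List &tree, const NumericMatrix &X,
                         std::vector<double> &out) {
  IntegerVector feature = tree["feature"], left = tree["left"],
    right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  for (int i = 0; i < X.nrow(); ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
    out[i] = value[node];
  }
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(List tree, NumericMatrix X) {
  std::vector<double> out(X.nrow());
  predict_tree(tree, X, out);
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
                    int min_split, int max_depth, int seed) {
  std::uint64_t rng = (std::uint64_t)seed * 6364136223846793005ULL + 12820163ULL;
  for (int k = 0; k < 8; ++k) xs64(rng);
  const int n = X.nrow();
  List forest(ntree);
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> samples(n);
    for (int i = 0; i < n; ++i) samples[i] = rand_below(rng, n);
    forest[b] = grow_tree_impl(X, y, samples, mtry, min_split, max_depth, rng);
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List forest, NumericMatrix X) {
  std::vector<double> acc(X.nrow(), 0.0), one(X.nrow());
  for (int b = 0; b < forest.size(); ++b) {
    predict_tree(forest[b], X, one);
    for (int i = 0; i < X.nrow(); ++i) acc[i] += one[i];
  }
  for (int i = 0; i < X.nrow(); ++i) acc[i] /= forest.size();
  return wrap(acc);
}
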