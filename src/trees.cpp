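// CART-style regression trees for the bagged-forest and gradient-boosting
// learners. Variance-reduction splits, depth / node-size limits, impurity
// importances. Randomness comes from R's RNG so results follow set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Flat node storage: feature (-1 = leaf), threshold, left, right, value.
struct Tree {
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;

  int add_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

// sample `m` distinct feature indices out of p (partial Fisher-Yates)
static void sample_features(int p, int m, std::vector<int>& pool,
                            std::vector<int>& out) {
  for (int i = 0; i < p; ++i) pool[i] = i;
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

struct Builder {
  const NumericMatrix& X;
  const std::vector<double>& y;
  int mtry, max_depth, min_node, min_leaf;
  Tree tree;
  std::vector<double> importance;  // SSE reduction per feature
  std::vector<int> pool, feats;
  std::vector<std::pair<double, double> > xy;  // (x value, y) sort buffer

  Builder(const NumericMatrix& X_, const std::vector<double>& y_, int mtry_,
          int max_depth_, int min_node_, int min_leaf_)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_), min_node(min_node_),
        min_leaf(min_leaf_), importance(X_.ncol(), 0.0), pool(X_.ncol()),
        feats(X_.ncol()) {}

  int build(std::vector<int>& idx, int lo, int hi, int depth) {
    int node = tree.add_node();
    int n = hi - lo;
    double sum = 0.0, sum2 = 0.0;
    for (int i = lo; i < hi; ++i) {
      sum += y[idx[i]];
      sum2 += y[idx[i]] * y[idx[i]];
    }
    double mean = sum / n;
    tree.value[node] = mean;
    double sse = sum2 - sum * sum / n;
    if (depth >= max_depth || n < min_node || sse <= 1e-12) return node;

    int m = std::min(mtry, (int)X.ncol());
    sample_features(X.ncol(), m, pool, feats);

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    for (int fi = 0; fi < m; ++fi) {
      int f = feats[fi];
      xy.resize(n);
      for (int i = 0; i < n; ++i) {
        xy[i].first = X(idx[lo + i], f);
        xy[i].second = y[idx[lo + i]];
      }
      std::sort(xy.begin(), xy.end());
      if (xy[0].first == xy[n - 1].first) continue;
      double ls = 0.0, ls2 = 0.0, rs = sum, rs2 = sum2;
      for (int i = 0; i < n - 1; ++i) {
        double yi = xy[i].second;
        ls += yi; ls2 += yi * yi;
        rs -= yi; rs2 -= yi * yi;
        int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        if (xy[i].first == xy[i + 1].first) continue;  // no cut between ties
        double gain = sse - (ls2 - ls * ls / nl) - (rs2 - rs * rs / nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node;

    // partition idx[lo, hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i) {
      if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
    }
    if (mid == lo || mid == hi) return node;  // numeric safety

    importance[best_f] += best_gain;
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    int l = build(idx, lo, mid, depth + 1);
    int r = build(idx, mid, hi, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

static NumericMatrix tree_to_matrix(const Tree& t) {
  int n = (int)t.feature.size();
  NumericMatrix m(n, 5);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = t.feature[i];
    m(i, 1) = t.threshold[i];
    m(i, 2) = t.left[i];
    m(i, 3) = t.right[i];
    m(i, 4) = t.value[i];
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "value");
  return m;
}

static double predict_row(const NumericMatrix& tr, const NumericMatrix& X,
                          int row) {
  int node = 0;
  while (tr(node, 0) >= 0) {
    node = (X(row, (int)tr(node, 0)) <= tr(node, 1)) ? (int)tr(node, 2)
                                                     : (int)tr(node, 3);
  }
  return tr(node, 4);
}

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int ntrees, int mtry,
                    int max_depth, int min_node) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> yy(y.begin(), y.end());
  List trees(ntrees);
  NumericVector imp(p);
  std::vector<int> idx(n);
  for (int t = 0; t < ntrees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = (int)(unif_rand() * n);  // bootstrap
    Builder b(X, yy, mtry, max_depth, min_node, 1);
    b.build(idx, 0, n, 0);
    trees[t] = tree_to_matrix(b.tree);
    for (int j = 0; j < p; ++j) imp[j] += b.importance[j];
  }
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_row(tr, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// [[Rcpp::export]]
List cpp_gbt_fit(NumericMatrix X, NumericVector y, int nrounds, int max_depth,
                 double shrinkage, int min_node, double subsample) {
  int n = X.nrow(), p = X.ncol();
  double init = mean(y);
  std::vector<double> resid(n), pred(n, init);
  List trees(nrounds);
  NumericVector imp(p);
  std::vector<int> idx;
  idx.reserve(n);
  for (int t = 0; t < nrounds; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - pred[i];
    idx.clear();
    if (subsample >= 1.0) {
      for (int i = 0; i < n; ++i) idx.push_back(i);
    } else {
      for (int i = 0; i < n; ++i)
        if (unif_rand() < subsample) idx.push_back(i);
      if ((int)idx.size() < std::max(2 * min_node, 4)) {
        idx.clear();
        for (int i = 0; i < n; ++i) idx.push_back(i);
      }
    }
    Builder b(X, resid, p, max_depth, min_node, 1);
    b.build(idx, 0, (int)idx.size(), 0);
    NumericMatrix tr = tree_to_matrix(b.tree);
    trees[t] = tr;
    for (int j = 0; j < p; ++j) imp[j] += b.importance[j];
    for (int i = 0; i < n; ++i) pred[i] += shrinkage * predict_row(tr, X, i);
  }
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["init"] = init, _["shrinkage"] = shrinkage);
}

// [[Rcpp::export]]
NumericVector cpp_gbt_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  double init = model["init"];
  double shrinkage = model["shrinkage"];
  int n = X.nrow(), T = trees.size();
  NumericVector out(n, init);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) out[i] += shrinkage * predict_row(tr, X, i);
  }
  return out;
}
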