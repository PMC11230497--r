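// Gradient-boosted regression trees (squared-error loss).
//
// Stage-wise additive fitting of depth-limited CART-style regression trees
// to residuals. Split search is exact: every midpoint between consecutive
// distinct feature values is scored by the reduction in sum of squared
// errors. Impurity decreases are accumulated per feature (MDI).
//
// Trees are returned to R as numeric matrices with one row per node:
// [feature (1-based, 0 = leaf), threshold, left, right, value]
// so fitted models are plain-text serializable.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature;      // 0-based, -1 for leaf
  double threshold;
  int left, right;  // 0-based node index, -1 for leaf
  double value;     // node mean of the working response
};

static int grow_node(const NumericMatrix& X, const std::vector<double>& y,
                     const std::vector<int>& idx, int depth, int max_depth,
                     int min_node, std::vector<Node>& nodes,
                     std::vector<double>& mdi) {
  const int n = (int)idx.size();
  double sum = 0.0, sum2 = 0.0;
  for (int i : idx) { sum += y[i]; sum2 += y[i] * y[i]; }
  const double node_val = sum / n;
  const double sse = sum2 - sum * sum / n;
  const int me = (int)nodes.size();
  nodes.push_back({-1, 0.0, -1, -1, node_val});
  if (depth >= max_depth || n < 2 * min_node || sse <= 1e-12) return me;

  const int p = X.ncol();
  int best_f = -1;
  double best_gain = 1e-12, best_thr = 0.0;
  std::vector<std::pair<double, double>> v(n);
  for (int f = 0; f < p; ++f) {
    for (int k = 0; k < n; ++k) v[k] = {X(idx[k], f), y[idx[k]]};
    std::sort(v.begin(), v.end());
    double lsum = 0.0, lsum2 = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      lsum += v[k].second;
      lsum2 += v[k].second * v[k].second;
      if (v[k].first == v[k + 1].first) continue;
      const int nl = k + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      const double rsum = sum - lsum, rsum2 = sum2 - lsum2;
      const double gain = sse - (lsum2 - lsum * lsum / nl)
                              - (rsum2 - rsum * rsum / nr);
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (v[k].first + v[k + 1].first);
      }
    }
  }
  if (best_f < 0) return me;

  std::vector<int> li, ri;
  li.reserve(n); ri.reserve(n);
  for (int i : idx) {
    if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
  }
  if (li.empty() || ri.empty()) return me;
  mdi[best_f] += best_gain;
  nodes[me].feature = best_f;
  nodes[me].threshold = best_thr;
  const int l = grow_node(X, y, li, depth + 1, max_depth, min_node, nodes, mdi);
  const int r = grow_node(X, y, ri, depth + 1, max_depth, min_node, nodes, mdi);
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

static NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix out((int)nodes.size(), 5);
  for (size_t k = 0; k < nodes.size(); ++k) {
    out(k, 0) = nodes[k].feature + 1;  // 1-based; 0 marks a leaf
    out(k, 1) = nodes[k].threshold;
    out(k, 2) = nodes[k].left + 1;
    out(k, 3) = nodes[k].right + 1;
    out(k, 4) = nodes[k].value;
  }
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value");
  return out;
}

static double predict_tree(const NumericMatrix& tree, const NumericMatrix& X,
                           int row) {
  int node = 0;
  for (;;) {
    const int f = (int)tree(node, 0);
    if (f == 0) return tree(node, 4);
    node = (X(row, f - 1) <= tree(node, 1)) ? (int)tree(node, 2) - 1
                                            : (int)tree(node, 3) - 1;
  }
}

// [[Rcpp::export(name = ".gbrt_fit_cpp")]]
List gbrt_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                  int max_depth, int min_node, double learning_rate) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X and y sizes differ");
  double init = 0.0;
  for (int i = 0; i < n; ++i) init += y[i];
  init /= n;

  std::vector<double> resid(n), fit(n, init);
  std::vector<double> mdi(p, 0.0);
  List trees(n_trees);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - fit[i];
    std::vector<Node> nodes;
    grow_node(X, resid, all, 0, max_depth, min_node, nodes, mdi);
    NumericMatrix packed = pack_tree(nodes);
    trees[t] = packed;
    for (int i = 0; i < n; ++i) {
      fit[i] += learning_rate * predict_tree(packed, X, i);
    }
  }
  return List::create(_["init"] = init, _["trees"] = trees,
                      _["mdi"] = NumericVector(mdi.begin(), mdi.end()),
                      _["learning_rate"] = learning_rate);
}

// [[Rcpp::export(name = ".gbrt_predict_cpp")]]
NumericVector gbrt_predict_cpp(List trees, double init, double learning_rate,
                               NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, init);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) {
      out[i] += learning_rate * predict_tree(tree, X, i);
    }
  }
  return out;
}
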