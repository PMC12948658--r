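// Small random-forest regressor with out-of-bag permutation importance.
// Used as the base learner of the shadow-feature selection wrapper; kept
// minimal on purpose (bootstrap + mtry CART trees, variance splitting).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;      // -1: leaf
  double threshold = 0.0;
  double value = 0.0;    // leaf prediction
  int left = -1, right = -1;
};

struct Tree {
  std::vector<Node> nodes;
};

// uniform integer in [0, n) from R's RNG
inline int runif_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

void grow(Tree& tree, int node_id, std::vector<int>& idx, int lo, int hi,
          const NumericMatrix& X, const NumericVector& y,
          int mtry, int min_node) {
  const int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int i = lo; i < hi; ++i) {
    sum += y[idx[i]];
    sum2 += y[idx[i]] * y[idx[i]];
  }
  const double mean = sum / n;
  tree.nodes[node_id].value = mean;
  const double sse = sum2 - sum * sum / n;
  if (n < 2 * min_node || sse <= 1e-12) return;

  const int p = X.ncol();
  // sample mtry features without replacement (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int best_f = -1;
  double best_gain = 1e-12, best_thr = 0.0;
  std::vector<std::pair<double, int>> vals(n);
  for (int t = 0; t < mtry && t < p; ++t) {
    int swap = t + runif_int(p - t);
    std::swap(feats[t], feats[swap]);
    const int f = feats[t];
    for (int i = 0; i < n; ++i)
      vals[i] = {X(idx[lo + i], f), idx[lo + i]};
    std::sort(vals.begin(), vals.end());
    double lsum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += y[vals[i].second];
      if (i + 1 < min_node || n - i - 1 < min_node) continue;
      if (vals[i + 1].first <= vals[i].first) continue;  // tied values
      const int nl = i + 1, nr = n - nl;
      const double rsum = sum - lsum;
      const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // partition idx[lo, hi) by the chosen split
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;

  tree.nodes[node_id].feature = best_f;
  tree.nodes[node_id].threshold = best_thr;
  tree.nodes.push_back(Node());
  tree.nodes.push_back(Node());
  const int l = static_cast<int>(tree.nodes.size()) - 2;
  tree.nodes[node_id].left = l;
  tree.nodes[node_id].right = l + 1;
  grow(tree, l, idx, lo, mid, X, y, mtry, min_node);
  grow(tree, l + 1, idx, mid, hi, X, y, mtry, min_node);
}

double predict_row(const Tree& tree, const NumericMatrix& X, int row,
                   const double* override_val, int override_feat) {
  int id = 0;
  while (tree.nodes[id].feature >= 0) {
    const int f = tree.nodes[id].feature;
    const double v = (f == override_feat && override_val) ? *override_val
                                                          : X(row, f);
    id = (v <= tree.nodes[id].threshold) ? tree.nodes[id].left
                                         : tree.nodes[id].right;
  }
  return tree.nodes[id].value;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "rf_importance_cpp")]]
List rf_importance_cpp(NumericMatrix X, NumericVector y,
                       int n_trees = 128, int mtry = 0, int min_node = 5) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 5) stop("need at least 5 observations");
  if (mtry <= 0) mtry = std::max(1, p / 3);
  if (mtry > p) mtry = p;

  NumericVector imp_sum(p), imp_sum2(p);
  NumericVector oob_pred(n), oob_count(n);
  std::vector<int> in_bag(n);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(in_bag.begin(), in_bag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = runif_int(n);
      in_bag[idx[i]] += 1;
    }
    Tree tree;
    tree.nodes.push_back(Node());
    grow(tree, 0, idx, 0, n, X, y, mtry, min_node);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (in_bag[i] == 0) oob.push_back(i);
    if (oob.empty()) continue;

    double base_mse = 0.0;
    for (int i : oob) {
      const double pr = predict_row(tree, X, i, nullptr, -1);
      base_mse += (y[i] - pr) * (y[i] - pr);
      oob_pred[i] += pr;
      oob_count[i] += 1.0;
    }
    base_mse /= oob.size();

    // permute each feature's OOB column, one at a time
    std::vector<double> col(oob.size());
    for (int f = 0; f < p; ++f) {
      for (size_t i = 0; i < oob.size(); ++i) col[i] = X(oob[i], f);
      for (size_t i = oob.size() - 1; i > 0; --i)
        std::swap(col[i], col[runif_int(static_cast<int>(i) + 1)]);
      double mse = 0.0;
      for (size_t i = 0; i < oob.size(); ++i) {
        const double v = col[i];
        const double pr = predict_row(tree, X, oob[i], &v, f);
        mse += (y[oob[i]] - pr) * (y[oob[i]] - pr);
      }
      mse /= oob.size();
      const double d = mse - base_mse;
      imp_sum[f] += d;
      imp_sum2[f] += d * d;
    }
  }

  NumericVector importance(p), imp_sd(p);
  for (int f = 0; f < p; ++f) {
    importance[f] = imp_sum[f] / n_trees;
    const double v = imp_sum2[f] / n_trees - importance[f] * importance[f];
    imp_sd[f] = v > 0 ? std::sqrt(v) : 0.0;
  }
  for (int i = 0; i < n; ++i)
    oob_pred[i] = oob_count[i] > 0 ? oob_pred[i] / oob_count[i] : NA_REAL;

  return List::create(_["importance"] = importance,
                      _["importance_sd"] = imp_sd,
                      _["oob_prediction"] = oob_pred);
}
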