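// Regression random forest: bagged CART with MSE-impurity splits.
// Kept minimal on purpose: mtry / max_depth are the only capacity controls
// the layer-2 tuning grid needs, impurity bookkeeping feeds MDI importance.
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // child node ids
  double value;     // leaf prediction (node mean)
};

struct WorkItem {
  int node_id;
  int start, end;   // index range into idx
  int depth;
};

inline int unif_index(int n) {
  // exact in [0, n): R_unif_index avoids modulo bias
  return static_cast<int>(R_unif_index(static_cast<double>(n)));
}

// Grow one tree on rows idx[start_all..end_all) of (X, y).
// Returns node arrays; accumulates impurity decreases into mdi.
void grow_tree(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& idx, int n_total, int mtry, int max_depth,
               int min_split, std::vector<Node>& nodes,
               std::vector<double>& mdi) {
  const int p = X.ncol();
  std::vector<int> feat_order(p);
  std::vector<std::pair<double, int> > buf;

  std::vector<WorkItem> stack;
  nodes.clear();
  nodes.push_back(Node());
  stack.push_back(WorkItem{0, 0, (int)idx.size(), 0});

  while (!stack.empty()) {
    WorkItem w = stack.back();
    stack.pop_back();
    const int n = w.end - w.start;

    double sum = 0.0, sum2 = 0.0;
    for (int i = w.start; i < w.end; ++i) {
      const double v = y[idx[i]];
      sum += v;
      sum2 += v * v;
    }
    const double mean = sum / n;
    const double sse = sum2 - sum * sum / n;

    Node& node = nodes[w.node_id];
    node.feature = -1;
    node.value = mean;
    node.left = node.right = -1;
    node.threshold = 0.0;

    const bool depth_ok = (max_depth <= 0) || (w.depth < max_depth);
    if (!depth_ok || n < min_split || sse <= 1e-12) continue;

    // sample mtry distinct features (partial Fisher-Yates)
    for (int j = 0; j < p; ++j) feat_order[j] = j;
    int best_feat = -1, best_pos = -1;
    double best_gain = 1e-12, best_thr = 0.0;
    std::vector<int> best_sorted;

    for (int draw = 0; draw < mtry; ++draw) {
      const int pick = draw + unif_index(p - draw);
      std::swap(feat_order[draw], feat_order[pick]);
      const int f = feat_order[draw];

      buf.resize(n);
      for (int i = 0; i < n; ++i) {
        const int r = idx[w.start + i];
        buf[i] = std::make_pair(X(r, f), r);
      }
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;

      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += y[buf[i].second];
        if (buf[i].first == buf[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        const double rsum = sum - lsum;
        const double gain =
            lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_pos = nl;
          best_thr = 0.5 * (buf[i].first + buf[i + 1].first);
          best_sorted.resize(n);
          for (int k = 0; k < n; ++k) best_sorted[k] = buf[k].second;
        }
      }
    }

    if (best_feat < 0) continue;

    // commit split: reorder idx range to sorted-by-best-feature order
    for (int k = 0; k < n; ++k) idx[w.start + k] = best_sorted[k];

    mdi[best_feat] += best_gain / n_total;

    const int left_id = (int)nodes.size();
    nodes.push_back(Node());
    const int right_id = (int)nodes.size();
    nodes.push_back(Node());
    Node& nd = nodes[w.node_id];  // re-fetch: push_back may reallocate
    nd.feature = best_feat;
    nd.threshold = best_thr;
    nd.left = left_id;
    nd.right = right_id;

    stack.push_back(WorkItem{right_id, w.start + best_pos, w.end, w.depth + 1});
    stack.push_back(WorkItem{left_id, w.start, w.start + best_pos, w.depth + 1});
  }
}

List pack_tree(const std::vector<Node>& nodes) {
  const int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int max_depth, int min_split, bool bootstrap) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  List trees(n_trees);
  std::vector<double> mdi(p, 0.0);
  std::vector<int> idx(n);
  std::vector<Node> nodes;

  for (int t = 0; t < n_trees; ++t) {
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = unif_index(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    grow_tree(X, y, idx, n, mtry, max_depth, min_split, nodes, mdi);
    trees[t] = pack_tree(nodes);
  }

  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = mdi[j] / n_trees;
  return List::create(_["trees"] = trees, _["mdi"] = importance);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector feature = tree["feature"];
    NumericVector threshold = tree["threshold"];
    IntegerVector left = tree["left"];
    IntegerVector right = tree["right"];
    NumericVector value = tree["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      out[i] += value[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
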