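// Regression-tree learner shared by the random-forest and
// gradient-boosted-tree model families. Splits maximise sum-of-squares
// reduction; on 0/1 targets this is proportional to the Gini decrease, so
// one learner serves probability forests and gradient boosting alike.
// All randomness (mtry feature draws) comes from R's RNG so set.seed()
// in R makes fits fully deterministic.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double thr;
  int left, right;  // node indices, -1 for leaf
  double value;     // mean response in node
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, max_depth, min_node;
  std::vector<Node> nodes;
  std::vector<double> importance;

  Builder(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
          int max_depth_, int min_node_)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_),
        min_node(min_node_), importance(X_.ncol(), 0.0) {}

  int build(std::vector<int>& rows, int depth) {
    int n = rows.size();
    double sum = 0.0;
    for (int r : rows) sum += y[r];
    double mean = sum / n;
    int self = nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, mean});

    if (depth >= max_depth || n < 2 * min_node) return self;
    double sq = 0.0;
    for (int r : rows) sq += (y[r] - mean) * (y[r] - mean);
    if (sq <= 1e-12) return self;

    int p = X.ncol();
    // sample mtry distinct features via partial Fisher-Yates on R's RNG
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }

    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    std::vector<std::pair<double, double> > xv(n);  // (x, y)
    double parent_score = sum * sum / n;
    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      for (int i = 0; i < n; ++i) xv[i] = std::make_pair(X(rows[i], f), y[rows[i]]);
      std::sort(xv.begin(), xv.end());
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xv[i].second;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        if (xv[i].first == xv[i + 1].first) continue;
        double sr = sum - sl;
        double gain = sl * sl / nl + sr * sr / nr - parent_score;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (xv[i].first + xv[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return self;

    std::vector<int> lrows, rrows;
    for (int r : rows) {
      if (X(r, best_feat) <= best_thr) lrows.push_back(r);
      else rrows.push_back(r);
    }
    if (lrows.empty() || rrows.empty()) return self;
    importance[best_feat] += best_gain;
    int li = build(lrows, depth + 1);
    int ri = build(rrows, depth + 1);
    nodes[self].feature = best_feat;
    nodes[self].thr = best_thr;
    nodes[self].left = li;
    nodes[self].right = ri;
    return self;
  }
};

// [[Rcpp::export]]
List cpp_build_tree(NumericMatrix X, NumericVector y, IntegerVector rows,
                    int mtry, int max_depth, int min_node) {
  std::vector<int> rr(rows.begin(), rows.end());
  Builder b(X, y, mtry, max_depth, min_node);
  b.build(rr, 0);
  int k = b.nodes.size();
  IntegerVector feature(k), left(k), right(k);
  NumericVector thr(k), value(k);
  for (int i = 0; i < k; ++i) {
    feature[i] = b.nodes[i].feature;
    thr[i] = b.nodes[i].thr;
    left[i] = b.nodes[i].left;
    right[i] = b.nodes[i].right;
    value[i] = b.nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["thr"] = thr,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value,
                      _["importance"] = NumericVector(b.importance.begin(),
                                                      b.importance.end()));
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector thr = tree["thr"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
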