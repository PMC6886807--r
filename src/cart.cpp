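// Regression CART used by the decision-tree, random-forest and
// gradient-boosting learners. Least-squares splits, midpoint thresholds,
// optional per-node feature subsampling (mtry) for forests.
#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <stack>
#include <vector>

using namespace Rcpp;

struct NodeJob {
  int node_id;
  int lo, hi;  // [lo, hi) range into the row-index buffer
  int depth;
};

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, NumericVector y, int max_depth, int min_split,
               int min_leaf, int mtry, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1) stop("cannot grow a tree on zero rows");
  if (mtry < 1 || mtry > p) mtry = p;

  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  std::mt19937 rng(static_cast<unsigned>(seed));

  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  std::stack<NodeJob> jobs;
  auto new_node = [&]() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  };

  jobs.push({new_node(), 0, n, 0});
  std::vector<std::pair<double, double>> buf;  // (x, y) sorted per feature

  while (!jobs.empty()) {
    NodeJob jb = jobs.top();
    jobs.pop();
    const int m = jb.hi - jb.lo;
    double sum = 0.0;
    for (int i = jb.lo; i < jb.hi; ++i) sum += y[rows[i]];
    const double mean = sum / m;
    value[jb.node_id] = mean;

    bool stop_here = (m < min_split) || (m < 2 * min_leaf) ||
                     (max_depth > 0 && jb.depth >= max_depth);
    if (!stop_here) {
      // homogeneous targets need no split
      bool same = true;
      for (int i = jb.lo + 1; i < jb.hi && same; ++i)
        if (y[rows[i]] != y[rows[jb.lo]]) same = false;
      stop_here = same;
    }
    if (stop_here) continue;

    // sample candidate features without replacement
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(feat_pool[j], feat_pool[pick(rng)]);
    }

    int best_f = -1;
    double best_thr = 0.0, best_gain = 0.0;
    const double total_ss = [&] {
      double s2 = 0.0;
      for (int i = jb.lo; i < jb.hi; ++i) {
        double d = y[rows[i]] - mean;
        s2 += d * d;
      }
      return s2;
    }();

    for (int jj = 0; jj < mtry; ++jj) {
      const int f = feat_pool[jj];
      buf.resize(m);
      for (int i = 0; i < m; ++i) {
        const int r = rows[jb.lo + i];
        buf[i] = {X(r, f), y[r]};
      }
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;
      double lsum = 0.0;
      for (int i = 0; i < m - 1; ++i) {
        lsum += buf[i].second;
        const int nl = i + 1, nr = m - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        if (buf[i].first == buf[i + 1].first) continue;  // tied x: no cut here
        const double rsum = sum - lsum;
        const double gain =
            lsum * lsum / nl + rsum * rsum / nr - sum * sum / m;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (buf[i].first + buf[i + 1].first);
        }
      }
    }

    if (best_f < 0 || total_ss <= 0.0) continue;

    // partition rows: x <= threshold goes left
    int mid = jb.lo;
    for (int i = jb.lo; i < jb.hi; ++i)
      if (X(rows[i], best_f) <= best_thr) std::swap(rows[i], rows[mid++]);
    if (mid == jb.lo || mid == jb.hi) continue;  // numeric safety

    feature[jb.node_id] = best_f;
    threshold[jb.node_id] = best_thr;
    const int lid = new_node(), rid = new_node();
    left[jb.node_id] = lid;
    right[jb.node_id] = rid;
    jobs.push({lid, jb.lo, mid, jb.depth + 1});
    jobs.push({rid, mid, jb.hi, jb.depth + 1});
  }

  return List::create(_["feature"] = wrap(feature),
                      _["threshold"] = wrap(threshold),
                      _["left"] = wrap(left), _["right"] = wrap(right),
                      _["value"] = wrap(value));
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    out[i] = value[node];
  }
  return out;
}
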