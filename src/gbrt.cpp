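// Least-squares gradient-boosted regression trees.
//
// Greedy top-down CART splits maximising squared-error reduction; split
// candidates are midpoints between consecutive distinct sorted feature
// values; ties between equal-gain splits resolve to the lowest feature
// index, then the lowest threshold (enforced by scan order with a
// strictly-greater comparison).  Leaf value = mean residual.  Routing at
// prediction time: left iff x[feature] <= threshold.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Tree {
  // parallel arrays; feature = -1 marks a leaf, child indices are 0-based,
  // -1 for leaves.
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;
};

static int grow_node(const NumericMatrix &X, const std::vector<double> &r,
                     std::vector<int> &idx, int lo, int hi, int depth,
                     int max_depth, int min_leaf, Tree &tree) {
  const int n = hi - lo;
  // long-double accumulation keeps split gains identical to R's sum()
  long double acc = 0.0L;
  double rmin = r[idx[lo]], rmax = r[idx[lo]];
  for (int t = lo; t < hi; ++t) {
    const double ri = r[idx[t]];
    acc += ri;
    if (ri < rmin) rmin = ri;
    if (ri > rmax) rmax = ri;
  }
  const double sum = (double)acc;
  const double mean = sum / n;

  int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(NA_REAL);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(mean);

  // zero-variance nodes are leaves: no split can reduce the error
  if (depth >= max_depth || n < 2 * min_leaf || rmin == rmax) return node;

  const int d = X.ncol();
  double best_gain = 0.0;  // must strictly improve on no split
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, double> > xv(n);  // (feature value, residual)
  for (int j = 0; j < d; ++j) {
    for (int t = 0; t < n; ++t) {
      const int i = idx[lo + t];
      xv[t] = std::make_pair(X(i, j), r[i]);
    }
    std::sort(xv.begin(), xv.end());
    long double sl_acc = 0.0L;
    for (int t = 1; t < n; ++t) {
      sl_acc += xv[t - 1].second;
      if (xv[t - 1].first >= xv[t].first) continue;  // not a distinct boundary
      const int nl = t, nr = n - t;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double sl = (double)sl_acc;
      const double sr = sum - sl;
      const double gain = sl * sl / nl + sr * sr / nr - sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = (xv[t - 1].first + xv[t].first) / 2.0;
      }
    }
  }

  if (best_feat < 0) return node;

  // partition idx[lo, hi) stably by the chosen split
  std::vector<int> lbuf, rbuf;
  lbuf.reserve(n);
  rbuf.reserve(n);
  for (int t = lo; t < hi; ++t) {
    if (X(idx[t], best_feat) <= best_thr) lbuf.push_back(idx[t]);
    else rbuf.push_back(idx[t]);
  }
  std::copy(lbuf.begin(), lbuf.end(), idx.begin() + lo);
  std::copy(rbuf.begin(), rbuf.end(), idx.begin() + lo + (int)lbuf.size());

  tree.feature[node] = best_feat;
  tree.threshold[node] = best_thr;
  int mid = lo + (int)lbuf.size();
  int l = grow_node(X, r, idx, lo, mid, depth + 1, max_depth, min_leaf, tree);
  int rt = grow_node(X, r, idx, mid, hi, depth + 1, max_depth, min_leaf, tree);
  tree.left[node] = l;
  tree.right[node] = rt;
  return node;
}

static Tree grow_tree(const NumericMatrix &X, const std::vector<double> &r,
                      int max_depth, int min_leaf) {
  const int n = X.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Tree tree;
  grow_node(X, r, idx, 0, n, 0, max_depth, min_leaf, tree);
  return tree;
}

static double predict_one(const Tree &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    node = (X(row, tree.feature[node]) <= tree.threshold[node])
               ? tree.left[node]
               : tree.right[node];
  }
  return tree.value[node];
}

static List tree_to_list(const Tree &tree) {
  return List::create(
      _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
      _["threshold"] = NumericVector(tree.threshold.begin(), tree.threshold.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["value"] = NumericVector(tree.value.begin(), tree.value.end()));
}

static Tree tree_from_list(const List &lst) {
  Tree tree;
  IntegerVector f = lst["feature"], l = lst["left"], r = lst["right"];
  NumericVector th = lst["threshold"], v = lst["value"];
  tree.feature.assign(f.begin(), f.end());
  tree.threshold.assign(th.begin(), th.end());
  tree.left.assign(l.begin(), l.end());
  tree.right.assign(r.begin(), r.end());
  tree.value.assign(v.begin(), v.end());
  return tree;
}

// [[Rcpp::export]]
List fit_tree_cpp(NumericMatrix X, NumericVector r, int max_depth, int min_leaf) {
  if (X.nrow() == 0) stop("empty input");
  std::vector<double> rv(r.begin(), r.end());
  return tree_to_list(grow_tree(X, rv, max_depth, min_leaf));
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  Tree t = tree_from_list(tree);
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = predict_one(t, X, i);
  return out;
}

// Boosting loop: r_m = y - f_{m-1}; T_m fit to r_m; f_m = f_{m-1} + eps T_m.
// Returns the trees, the final training scores and the per-iteration
// training MSE so monotonicity can be inspected without refitting.
// [[Rcpp::export]]
List fit_gbrt_cpp(NumericMatrix X, NumericVector y, int n_trees, double shrinkage,
                  int max_depth, int min_leaf, double base_score) {
  const int n = X.nrow();
  if (n == 0) stop("empty input");
  std::vector<double> f(n, base_score), resid(n);
  List trees(n_trees);
  NumericVector mse(n_trees);
  for (int m = 0; m < n_trees; ++m) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - f[i];
    Tree t = grow_tree(X, resid, max_depth, min_leaf);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      f[i] += shrinkage * predict_one(t, X, i);
      const double e = y[i] - f[i];
      sse += e * e;
    }
    mse[m] = sse / n;
    trees[m] = tree_to_list(t);
    if (m % 100 == 99) Rcpp::checkUserInterrupt();
  }
  return List::create(_["trees"] = trees,
                      _["train_scores"] = NumericVector(f.begin(), f.end()),
                      _["mse_path"] = mse);
}

// [[Rcpp::export]]
NumericVector predict_gbrt_cpp(List trees, NumericMatrix X, double shrinkage,
                               double base_score) {
  const int n = X.nrow();
  NumericVector out(n, base_score);
  for (int m = 0; m < trees.size(); ++m) {
    Tree t = tree_from_list(trees[m]);
    for (int i = 0; i < n; ++i) out[i] += shrinkage * predict_one(t, X, i);
  }
  return out;
}
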