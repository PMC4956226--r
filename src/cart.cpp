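#include <Rcpp.h>
using namespace Rcpp;

// Weighted binary CART (Gini impurity) for labels in {-1, +1}.
// Supports per-sample weights, depth limit, minimum node size and mtry
// (random feature subsampling per node, drawn from R's RNG stream so that
// set.seed() in R makes fits reproducible). Trees are returned flattened.

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // split: x <= threshold goes left
  std::vector<int> left, right;
  std::vector<double> pred;      // leaf prediction in {-1, +1}
  std::vector<double> imp;       // per-feature impurity decrease
};

static double gini_node(double wpos, double wtot) {
  if (wtot <= 0) return 0.0;
  double p = wpos / wtot;
  return 2.0 * p * (1.0 - p);
}

static int build_node(const NumericMatrix &X, const IntegerVector &y,
                      const NumericVector &w, std::vector<int> &idx,
                      int lo, int hi, int depth, int max_depth,
                      double min_node_w, int min_node_n, int mtry,
                      TreeBuf &tb) {
  int node = (int)tb.feature.size();
  tb.feature.push_back(-1);
  tb.threshold.push_back(0.0);
  tb.left.push_back(-1);
  tb.right.push_back(-1);
  tb.pred.push_back(1.0);

  double wtot = 0.0, wpos = 0.0;
  for (int t = lo; t < hi; ++t) {
    wtot += w[idx[t]];
    if (y[idx[t]] > 0) wpos += w[idx[t]];
  }
  // majority vote, ties to +1
  tb.pred[node] = (wpos >= wtot - wpos) ? 1.0 : -1.0;

  int n = hi - lo;
  double g0 = gini_node(wpos, wtot);
  if (depth >= max_depth || n < 2 * min_node_n || wtot <= 2 * min_node_w ||
      g0 <= 0.0)
    return node;

  int p = X.ncol();
  // choose mtry features without replacement via partial Fisher-Yates
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int r = j + (int)std::floor(unif_rand() * (p - j));
    if (r >= p) r = p - 1;
    std::swap(feats[j], feats[r]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<std::pair<double, int> > vals(n);
  for (int jj = 0; jj < m; ++jj) {
    int f = feats[jj];
    for (int t = 0; t < n; ++t)
      vals[t] = std::make_pair(X(idx[lo + t], f), idx[lo + t]);
    std::sort(vals.begin(), vals.end());
    double wl = 0.0, wlpos = 0.0;
    for (int t = 0; t < n - 1; ++t) {
      int i = vals[t].second;
      wl += w[i];
      if (y[i] > 0) wlpos += w[i];
      if (vals[t + 1].first <= vals[t].first) continue; // not a cut point
      double wr = wtot - wl, wrpos = wpos - wlpos;
      if (wl < min_node_w || wr < min_node_w) continue;
      if (t + 1 < min_node_n || n - t - 1 < min_node_n) continue;
      double gain = wtot * g0 - wl * gini_node(wlpos, wl) -
                    wr * gini_node(wrpos, wr);
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo:hi) in place
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_f) <= best_thr) std::swap(idx[t], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  tb.feature[node] = best_f;
  tb.threshold[node] = best_thr;
  tb.imp[best_f] += best_gain;
  int l = build_node(X, y, w, idx, lo, mid, depth + 1, max_depth, min_node_w,
                     min_node_n, mtry, tb);
  int r = build_node(X, y, w, idx, mid, hi, depth + 1, max_depth, min_node_w,
                     min_node_n, mtry, tb);
  tb.left[node] = l;
  tb.right[node] = r;
  return node;
}

// [[Rcpp::export(name = ".cart_fit")]]
List cart_fit(NumericMatrix X, IntegerVector y, NumericVector w,
              int max_depth, int min_node, int mtry) {
  RNGScope scope;
  int n = X.nrow();
  TreeBuf tb;
  tb.imp.assign(X.ncol(), 0.0);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  build_node(X, y, w, idx, 0, n, 0, max_depth, 0.0, min_node, mtry, tb);
  return List::create(_["feature"] = wrap(tb.feature),
                      _["threshold"] = wrap(tb.threshold),
                      _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
                      _["pred"] = wrap(tb.pred),
                      _["importance"] = wrap(tb.imp));
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector pred = tree["pred"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
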