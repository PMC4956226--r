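#include <Rcpp.h>
using namespace Rcpp;

// C-SVC with RBF kernel solved by SMO with maximal-violating-pair working
// set selection (LIBSVM-style; the kernel matrix is held dense, intended
// for the moderate training sizes of segment-level ECG datasets).
//
// Dual: min_a 0.5 a'Qa - e'a, 0 <= a_i <= C, y'a = 0, Q_ij = y_i y_j K_ij.
// Working in z_t = y_t a_t coordinates the update direction is
// (dz_i, dz_j) = (+d, -d) with optimal d = (gmax - gmin)/eta,
// eta = K_ii + K_jj - 2 K_ij, where gmax = -y_i G_i over the up-feasible
// set and gmin = -y_j G_j over the low-feasible set.

// [[Rcpp::export(name = ".svm_fit")]]
List svm_fit(NumericMatrix X, NumericVector y, double C, double gamma,
             double eps, int max_iter) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    K(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < p; ++k) {
        double t = X(i, k) - X(j, k);
        d += t * t;
      }
      double v = std::exp(-gamma * d);
      K(i, j) = v;
      K(j, i) = v;
    }
  }
  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G_i = (Qa)_i - 1
  int iter = 0;
  while (iter < max_iter) {
    int i = -1, j = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 1e-12) eta = 1e-12;
    double d = (gmax - gmin) / eta;

    double zi = y[i] * alpha[i] + d;
    double zj = y[j] * alpha[j] - d;
    // box: z in [0, C] when y > 0, [-C, 0] when y < 0; zi + zj conserved
    double zi_hi = y[i] > 0 ? C : 0.0, zj_lo = y[j] > 0 ? 0.0 : -C;
    if (zi > zi_hi) { zj += zi - zi_hi; zi = zi_hi; }
    if (zj < zj_lo) { zi += zj - zj_lo; zj = zj_lo; }

    double ai = y[i] * zi, aj = y[j] * zj;
    double dai = ai - alpha[i], daj = aj - alpha[j];
    if (std::fabs(dai) < 1e-15 && std::fabs(daj) < 1e-15) break;
    alpha[i] = ai;
    alpha[j] = aj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(i, t) * dai + y[j] * K(j, t) * daj);
    ++iter;
  }
  // intercept: b = -y_i G_i averaged over free SVs, else midpoint rule
  double bsum = 0.0, ub = 1e300, lb = -1e300;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { bsum += v; ++nfree; }
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool lo = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
    if (up) ub = std::min(ub, v);
    if (lo) lb = std::max(lb, v);
  }
  double b = nfree > 0 ? bsum / nfree : 0.5 * (ub + lb);
  return List::create(_["alpha"] = wrap(alpha), _["b"] = b,
                      _["iter"] = iter);
}

// [[Rcpp::export(name = ".svm_decision")]]
NumericVector svm_decision(NumericMatrix Xtrain, NumericVector y,
                           NumericVector alpha, double b, double gamma,
                           NumericMatrix Xnew) {
  int n = Xtrain.nrow(), p = Xtrain.ncol(), m = Xnew.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double s = b;
    for (int j = 0; j < n; ++j) {
      if (alpha[j] <= 0) continue;
      double d = 0.0;
      for (int k = 0; k < p; ++k) {
        double t = Xnew(i, k) - Xtrain(j, k);
        d += t * t;
      }
      s += alpha[j] * y[j] * std::exp(-gamma * d);
    }
    out[i] = s;
  }
  return out;
}
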