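#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. a[0] must be 1.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double yi = bb[0] * x[i] + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz; ++k) {
      double znext = (k + 1 < nz) ? z[k + 1] : 0.0;
      z[k] = bb[k + 1] * x[i] + znext - aa[k + 1] * yi;
    }
    y[i] = yi;
  }
  return y;
}

// Sample entropy, Chebyshev distance, template length m, tolerance r
// (absolute units). Self-matches excluded. Returns -log(A/B); if A or B
// is zero returns NA.
// [[Rcpp::export(name = ".sampen")]]
double sampen(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) return NA_REAL;
  long long A = 0, B = 0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        d = std::fabs(x[i + k] - x[j + k]);
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

// Lempel-Ziv 1976 complexity (Kaspar-Schuster counting) of a 0/1 sequence.
// [[Rcpp::export(name = ".lz_complexity")]]
int lz_complexity(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
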