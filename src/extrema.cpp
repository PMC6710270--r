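#include <Rcpp.h>
using namespace Rcpp;

// van Herk / Gil-Werman running extrema with a centred flat window of odd
// width w (edge-replicated). O(n) per call; the kernel behind morphological
// erosion/dilation for TopHat baseline subtraction.
static NumericVector running_extremum(const NumericVector& x, int w, bool mn) {
  int n = x.size();
  if (w <= 1 || n == 0) return clone(x);
  int r = w / 2;
  int m = n + 2 * r;                 // padded length
  std::vector<double> p(m);
  for (int i = 0; i < m; ++i) {
    int j = i - r;
    if (j < 0) j = 0;
    if (j > n - 1) j = n - 1;
    p[i] = x[j];
  }
  std::vector<double> g(m), h(m);
  for (int i = 0; i < m; ++i) {
    if (i % w == 0) g[i] = p[i];
    else g[i] = mn ? std::min(g[i - 1], p[i]) : std::max(g[i - 1], p[i]);
  }
  for (int i = m - 1; i >= 0; --i) {
    if (i == m - 1 || (i + 1) % w == 0) h[i] = p[i];
    else h[i] = mn ? std::min(h[i + 1], p[i]) : std::max(h[i + 1], p[i]);
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int lo = i, hi = i + 2 * r;      // window [lo, hi] in padded coords
    double a = h[lo], b = g[hi];
    out[i] = mn ? std::min(a, b) : std::max(a, b);
  }
  return out;
}

// [[Rcpp::export(name = ".running_min")]]
NumericVector running_min_cpp(NumericVector x, int w) {
  return running_extremum(x, w, true);
}

// [[Rcpp::export(name = ".running_max")]]
NumericVector running_max_cpp(NumericVector x, int w) {
  return running_extremum(x, w, false);
}
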