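#include <Rcpp.h>
using namespace Rcpp;

// MODWT pyramid with circular boundary. Filters g (scaling) and h
// (wavelet) are the unit-norm DWT filters rescaled by 1/sqrt(2); level-j
// filtering uses the filter upsampled by 2^(j-1). Loops are tap-major so
// every pass over the series is contiguous (cache-friendly): for tap l
// the shifted source v[(t - l*step) mod n] splits into two contiguous
// segments of v.

static void filterPass(const std::vector<double>& v, double coef,
                       int shift, int n, std::vector<double>& acc) {
  // acc[t] += coef * v[(t - shift) mod n], 0 <= shift < n
  const double* src = v.data();
  double* dst = acc.data();
  // t in [shift, n): source index t - shift in [0, n - shift)
  for (int t = shift, s = 0; t < n; ++t, ++s) dst[t] += coef * src[s];
  // t in [0, shift): source index t - shift + n in [n - shift, n)
  for (int t = 0, s = n - shift; t < shift; ++t, ++s) dst[t] += coef * src[s];
}

// [[Rcpp::export(name = ".modwtForwardCpp")]]
List modwtForwardCpp(NumericVector x, NumericVector g, NumericVector h,
                     int J) {
  const int n = x.size(), L = g.size();
  List W(J);
  std::vector<double> v(x.begin(), x.end()), vnext(n), w(n);
  for (int j = 0; j < J; ++j) {
    const int step = 1 << j;
    std::fill(w.begin(), w.end(), 0.0);
    std::fill(vnext.begin(), vnext.end(), 0.0);
    for (int l = 0; l < L; ++l) {
      const int shift = (int)(((long long)l * step) % n);
      filterPass(v, h[l], shift, n, w);
      filterPass(v, g[l], shift, n, vnext);
    }
    W[j] = NumericVector(w.begin(), w.end());
    std::swap(v, vnext);
  }
  return List::create(_["W"] = W,
                      _["V"] = NumericVector(v.begin(), v.end()));
}

static void filterPassBack(const std::vector<double>& v, double coef,
                           int shift, int n, std::vector<double>& acc) {
  // acc[t] += coef * v[(t + shift) mod n], 0 <= shift < n
  const double* src = v.data();
  double* dst = acc.data();
  for (int t = 0, s = shift; t < n - shift; ++t, ++s) dst[t] += coef * src[s];
  for (int t = n - shift, s = 0; t < n; ++t, ++s) dst[t] += coef * src[s];
}

// [[Rcpp::export(name = ".modwtInverseCpp")]]
NumericVector modwtInverseCpp(List W, NumericVector V, NumericVector g,
                              NumericVector h) {
  const int J = W.size(), n = V.size(), L = g.size();
  std::vector<double> v(V.begin(), V.end()), vprev(n);
  for (int j = J - 1; j >= 0; --j) {
    NumericVector wjr = W[j];
    std::vector<double> wj(wjr.begin(), wjr.end());
    const int step = 1 << j;
    std::fill(vprev.begin(), vprev.end(), 0.0);
    for (int l = 0; l < L; ++l) {
      const int shift = (int)(((long long)l * step) % n);
      filterPassBack(wj, h[l], shift, n, vprev);
      filterPassBack(v, g[l], shift, n, vprev);
    }
    std::swap(v, vprev);
  }
  return NumericVector(v.begin(), v.end());
}
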