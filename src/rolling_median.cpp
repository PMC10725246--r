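#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Centered rolling median with an arbitrary (possibly even) window.
// For window w the centered span at position i is [i - w/2, i + w/2 - 1]
// (one extra sample on the left for even w); at the edges the window
// shrinks to the available samples. An even number of samples in the
// window yields the mean of the two central order statistics.
// [[Rcpp::export(.rolling_median)]]
NumericVector rolling_median(NumericVector x, int window) {
  const int n = x.size();
  if (window < 1) stop("window must be >= 1");
  NumericVector out(n);
  const int left = window / 2;
  const int right = window - left - 1;
  std::vector<double> buf;
  buf.reserve(window);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - left);
    int hi = std::min(n - 1, i + right);
    int m = hi - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    int mid = m / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double med = buf[mid];
    if (m % 2 == 0) {
      double lower = *std::max_element(buf.begin(), buf.begin() + mid);
      med = (med + lower) / 2.0;
    }
    out[i] = med;
  }
  return out;
}
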