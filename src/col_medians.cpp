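#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Column medians of a numeric matrix. Hot path of the cell-level
// bootstrap in crosstalk_effect(), where population median trajectories
// are recomputed thousands of times.
// [[Rcpp::export]]
NumericVector col_medians_cpp(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  if (n == 0) stop("empty matrix");
  NumericVector out(p);
  std::vector<double> buf(n);
  const int h = n / 2;
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = x(i, j);
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (n % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = (m + lo) / 2.0;
    }
    out[j] = m;
  }
  return out;
}
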