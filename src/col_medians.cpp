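#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Columnwise medians with the even-size convention "mean of the two middle
// values". Hot path of the center update, called once per cluster per sweep.
// [[Rcpp::export]]
NumericVector col_medians(NumericMatrix x) {
  const int m = x.nrow(), n = x.ncol();
  NumericVector out(n);
  if (m == 0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  std::vector<double> buf(m);
  const int h = m / 2;
  for (int j = 0; j < n; ++j) {
    NumericMatrix::Column col = x(_, j);
    std::copy(col.begin(), col.end(), buf.begin());
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (m % 2 == 0) {
      double lower = *std::max_element(buf.begin(), buf.begin() + h);
      med = (med + lower) / 2.0;
    }
    out[j] = med;
  }
  return out;
}
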