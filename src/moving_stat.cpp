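#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// NA-aware sliding-window statistic with shrinking edge windows.
// Output i = stat over non-missing x[max(0,i-h) .. min(n-1,i+h)];
// all-missing window -> NA. Symmetric window => zero phase shift.
// [[Rcpp::export]]
NumericVector moving_stat_cpp(NumericVector x, int halfwidth,
                              std::string stat) {
  const int n = x.size();
  if (halfwidth < 0) stop("halfwidth must be >= 0");
  const bool use_median = (stat == "median");
  if (!use_median && stat != "mean") stop("unknown statistic '%s'", stat);

  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(2 * halfwidth + 1);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - halfwidth);
    const int hi = std::min(n - 1, i + halfwidth);
    buf.clear();
    double sum = 0.0;
    for (int j = lo; j <= hi; ++j) {
      const double v = x[j];
      if (!ISNAN(v)) {
        buf.push_back(v);
        sum += v;
      }
    }
    const int m = (int)buf.size();
    if (m == 0) {
      out[i] = NA_REAL;
    } else if (!use_median) {
      out[i] = sum / m;
    } else {
      const int mid = m / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (m % 2 == 0) {
        const double lower =
            *std::max_element(buf.begin(), buf.begin() + mid);
        med = (med + lower) / 2.0;
      }
      out[i] = med;
    }
  }
  return out;
}
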