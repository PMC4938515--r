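#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Matheron semivariance accumulator: all point pairs binned by Euclidean
// distance into half-open bins [k*w, (k+1)*w) up to max_lag. Returns per-bin
// sum of squared differences and pair counts; gamma(h) = sum / (2 * n).
// [[Rcpp::export]]
List cpp_variogram_bins(NumericVector x, NumericVector y, NumericVector z,
                        double lag_width, double max_lag) {
  const int n = x.size();
  const int nbins = (int)std::ceil(max_lag / lag_width);
  NumericVector ss(nbins);
  NumericVector np(nbins);
  const double max2 = max_lag * max_lag;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x[j], dy = yi - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 >= max2) continue;
      const int b = (int)(std::sqrt(d2) / lag_width);
      if (b >= nbins) continue;
      const double dz = zi - z[j];
      ss[b] += dz * dz;
      np[b] += 1.0;
    }
  }
  return List::create(_["ss"] = ss, _["n"] = np);
}
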