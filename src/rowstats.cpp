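#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Per-row summary statistics over a windows-by-hours block.
// Columns of the result: mean, median, min, max, population SD,
// adjusted Fisher-Pearson skewness (0 for constant rows or n < 3).
// [[Rcpp::export]]
NumericMatrix row_stats(const NumericMatrix& x) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, 6);
  std::vector<double> buf(p);
  for (int i = 0; i < n; ++i) {
    double s = 0.0, mn = x(i, 0), mx = x(i, 0);
    for (int j = 0; j < p; ++j) {
      const double v = x(i, j);
      buf[j] = v;
      s += v;
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    const double mean = s / p;
    double m2 = 0.0, m3 = 0.0;
    for (int j = 0; j < p; ++j) {
      const double d = buf[j] - mean;
      m2 += d * d;
      m3 += d * d * d;
    }
    m2 /= p;
    m3 /= p;
    std::sort(buf.begin(), buf.end());
    const double med = (p % 2) ? buf[p / 2]
                               : 0.5 * (buf[p / 2 - 1] + buf[p / 2]);
    double skew = 0.0;
    if (p >= 3 && m2 > 0.0) {
      const double g1 = m3 / std::pow(m2, 1.5);
      skew = g1 * std::sqrt((double)p * (p - 1)) / (p - 2);
    }
    out(i, 0) = mean;
    out(i, 1) = med;
    out(i, 2) = mn;
    out(i, 3) = mx;
    out(i, 4) = std::sqrt(m2);
    out(i, 5) = skew;
  }
  return out;
}

// Per-row Gini coefficient: G = sum_{i,j} |x_i - x_j| / (2 n^2 mean),
// computed via the sorted-order identity; defined as 0 when the row mean is 0.
// [[Rcpp::export]]
NumericVector row_gini(const NumericMatrix& x) {
  const int n = x.nrow(), p = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(p);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) {
      buf[j] = x(i, j);
      s += buf[j];
    }
    const double mean = s / p;
    if (mean == 0.0) {
      out[i] = 0.0;
      continue;
    }
    std::sort(buf.begin(), buf.end());
    double acc = 0.0;
    for (int j = 0; j < p; ++j) acc += (2.0 * (j + 1) - p - 1) * buf[j];
    out[i] = acc / ((double)p * p * mean);
  }
  return out;
}
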