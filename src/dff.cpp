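#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding-baseline dF/F for one trace.
// F0 at frame i (0-based) = mean of the ceil(fraction * w) smallest values
// among the w = min(window, i) preceding frames; frame 0 returns 0.
// [[Rcpp::export]]
NumericVector dff_sliding_cpp(NumericVector trace, int window, double fraction) {
  int n = trace.size();
  NumericVector out(n);
  if (n == 0) return out;
  std::vector<double> buf;
  buf.reserve(window);
  for (int i = 1; i < n; ++i) {
    int w = std::min(window, i);
    int k = (int)std::ceil(fraction * w);
    if (k < 1) k = 1;
    if (k > w) k = w;
    buf.assign(trace.begin() + (i - w), trace.begin() + i);
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += buf[j];
    double f0 = s / k;
    if (f0 <= 0.0)
      stop("non-positive baseline F0 at frame %d: input must be positive fluorescence", i + 1);
    out[i] = (trace[i] - f0) / f0;
  }
  return out;
}

// Row-wise version for a voxels x frames matrix.
// [[Rcpp::export]]
NumericMatrix dff_sliding_matrix_cpp(NumericMatrix traces, int window, double fraction) {
  int nr = traces.nrow(), nc = traces.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> row(nc), buf;
  buf.reserve(window);
  for (int r = 0; r < nr; ++r) {
    for (int j = 0; j < nc; ++j) row[j] = traces(r, j);
    for (int i = 1; i < nc; ++i) {
      int w = std::min(window, i);
      int k = (int)std::ceil(fraction * w);
      if (k < 1) k = 1;
      if (k > w) k = w;
      buf.assign(row.begin() + (i - w), row.begin() + i);
      std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += buf[j];
      double f0 = s / k;
      if (f0 <= 0.0)
        stop("non-positive baseline F0 at voxel %d frame %d: input must be positive fluorescence",
             r + 1, i + 1);
      out(r, i) = (row[i] - f0) / f0;
    }
  }
  return out;
}
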