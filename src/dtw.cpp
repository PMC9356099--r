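#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping alignment cost between two (possibly multivariate)
// sequences. X is n x d, Y is m x d. Admissible paths are monotone index
// sequences starting at (0,0), ending at (n-1,m-1), with unit steps
// (1,0), (0,1) or (1,1). The accumulated cost is the sum of squared
// Euclidean point distances along the path; the reported distance is the
// square root of the minimal accumulated cost.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericMatrix X, NumericMatrix Y) {
  const int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  if (n == 0 || m == 0) stop("empty sequence");
  if (Y.ncol() != d) stop("dimension mismatch");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = X(i, k) - Y(j, k);
        c += diff * diff;
      }
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else if (i == 0) best = cur[j - 1];
      else if (j == 0) best = prev[j];
      else {
        best = prev[j];                      // (1,0)
        if (cur[j - 1] < best) best = cur[j - 1];   // (0,1)
        if (prev[j - 1] < best) best = prev[j - 1]; // (1,1)
      }
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
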