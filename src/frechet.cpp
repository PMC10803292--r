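#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Discrete Frechet distance between two polylines given as n x 2 and m x 2
// coordinate matrices. Standard O(n*m) dynamic programme with a rolling row:
// ca(i,j) = max(d(i,j), min(ca(i-1,j), ca(i-1,j-1), ca(i,j-1))).
// [[Rcpp::export(name = ".frechet_dp")]]
double frechet_dp(NumericMatrix p, NumericMatrix q) {
  const int n = p.nrow(), m = q.nrow();
  if (n == 0 || m == 0) stop("empty polyline");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double dx = p(i, 0) - q(j, 0);
      const double dy = p(i, 1) - q(j, 1);
      const double d = std::sqrt(dx * dx + dy * dy);
      double reach;
      if (i == 0 && j == 0) {
        reach = d;
      } else if (i == 0) {
        reach = std::max(cur[j - 1], d);
      } else if (j == 0) {
        reach = std::max(prev[0], d);
      } else {
        const double best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
        reach = std::max(best, d);
      }
      cur[j] = reach;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
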