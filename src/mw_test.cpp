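#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// One-sided Mann-Whitney p-values (first n1 rows > remaining rows), one test
// per column, normal approximation with tie correction and continuity
// correction -- the same approximation wilcox.test() uses when exact = FALSE.
// [[Rcpp::export(name = ".mw_greater_pvals_cpp")]]
NumericVector mw_greater_pvals_cpp(NumericMatrix mat, int n1) {
  const int n = mat.nrow();
  const int G = mat.ncol();
  const int n2 = n - n1;
  if (n1 < 1 || n2 < 1) stop("both groups need at least one observation");
  NumericVector out(G);
  std::vector<std::pair<double, int>> buf(n);
  const double mu = (double)n1 * n2 / 2.0;

  for (int j = 0; j < G; ++j) {
    const double *col = &mat(0, j);
    for (int i = 0; i < n; ++i) buf[i] = {col[i], i < n1 ? 1 : 0};
    std::sort(buf.begin(), buf.end(),
              [](const std::pair<double, int> &a,
                 const std::pair<double, int> &b) { return a.first < b.first; });
    double tie_term = 0.0, rsum = 0.0;
    int i = 0;
    while (i < n) {
      int k = i;
      int targets = buf[i].second;
      while (k + 1 < n && buf[k + 1].first == buf[i].first) {
        ++k;
        targets += buf[k].second;
      }
      const double t = k - i + 1;
      const double avg = (i + 1 + k + 1) / 2.0;
      rsum += avg * targets;
      tie_term += t * t * t - t;
      i = k + 1;
    }
    const double U = rsum - (double)n1 * (n1 + 1) / 2.0;
    const double sigma2 = ((double)n1 * n2 / 12.0) *
      ((n + 1) - tie_term / ((double)n * (n - 1)));
    if (sigma2 <= 0.0) {
      out[j] = 1.0;  // every value tied across both groups
    } else {
      const double z = (U - mu - 0.5) / std::sqrt(sigma2);
      out[j] = R::pnorm(z, 0.0, 1.0, 0, 0);
    }
  }
  return out;
}
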