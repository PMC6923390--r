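#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Column-wise Mann-Whitney ingredients for two-group screening.
// For each column of X (subjects x features): the U statistic of group 1
// (rows where g1 is true), the tie correction sum(t^3 - t) over tied
// groups, and whether any tie exists. Mid-ranks are used throughout.

// [[Rcpp::export]]
List cpp_wmw_stats(NumericMatrix X, LogicalVector g1) {
  const int n = X.nrow(), p = X.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i) if (g1[i]) ++n1;
  NumericVector u(p), tiecorr(p);
  LogicalVector hasTies(p);
  std::vector<std::pair<double,int> > v(n);
  std::vector<double> ranks(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) v[i] = std::make_pair(X(i, j), i);
    std::sort(v.begin(), v.end());
    double tc = 0.0;
    bool ties = false;
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && v[k + 1].first == v[i].first) ++k;
      const double t = k - i + 1;
      const double midrank = (i + k) / 2.0 + 1.0;
      for (int q = i; q <= k; ++q) ranks[v[q].second] = midrank;
      if (t > 1) { ties = true; tc += t * t * t - t; }
      i = k + 1;
    }
    double r1 = 0.0;
    for (int q = 0; q < n; ++q) if (g1[q]) r1 += ranks[q];
    u[j] = r1 - n1 * (n1 + 1.0) / 2.0;
    tiecorr[j] = tc;
    hasTies[j] = ties;
  }
  return List::create(_["u"] = u, _["tiecorr"] = tiecorr,
                      _["hasTies"] = hasTies, _["n1"] = n1,
                      _["n2"] = n - n1);
}
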