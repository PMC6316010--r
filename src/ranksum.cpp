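#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Column-wise Mann-Whitney building blocks: the U statistic for the "case"
// group (computed from midranks), the tie term sum(t^3 - t) needed for the
// variance correction of the normal approximation, and a per-column tie flag.
// Splitting the p-value computation between C++ (statistics) and R
// (exact/approximate distribution) keeps fold-wise selection over tens of
// thousands of wavelet coefficients fast.
// [[Rcpp::export]]
List col_ranksum(NumericMatrix x, LogicalVector is_case) {
  const int n = x.nrow(), p = x.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i)
    if (is_case[i]) ++n1;
  NumericVector U(p), tie_term(p);
  LogicalVector has_ties(p);
  std::vector<int> ord(n);
  std::vector<double> v(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) v[i] = x(i, j);
    std::iota(ord.begin(), ord.end(), 0);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return v[a] < v[b]; });
    double r1 = 0.0, ties = 0.0;
    bool anyt = false;
    int i = 0;
    while (i < n) {
      int k = i + 1;
      while (k < n && v[ord[k]] == v[ord[i]]) ++k;
      const int t = k - i;
      const double mid = 0.5 * (i + k - 1) + 1.0; // 1-based midrank
      if (t > 1) {
        anyt = true;
        ties += static_cast<double>(t) * t * t - t;
      }
      for (int m = i; m < k; ++m)
        if (is_case[ord[m]]) r1 += mid;
      i = k;
    }
    U[j] = r1 - n1 * (n1 + 1.0) / 2.0;
    tie_term[j] = ties;
    has_ties[j] = anyt;
  }
  return List::create(_["U"] = U, _["tie_term"] = tie_term,
                      _["has_ties"] = has_ties, _["n_case"] = n1,
                      _["n_control"] = n - n1);
}
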