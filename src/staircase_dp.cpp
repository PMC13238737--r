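#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact weighted L1-optimal monotone upper set for binary labels, with the
// prediction region nondecreasing in both coordinates.
//
// A monotone upper set restricted to the data is fully described by one
// y-threshold per distinct x-value ("column"), the thresholds nonincreasing
// as x grows. Thresholds are drawn from the observed y-values plus +Inf
// (column entirely below the boundary). The DP scans columns left to right;
// B[j][q] is the optimal cost of columns j..m-1 given column j uses
// threshold index q (q smaller = lower threshold = larger upper set).
// Reconstruction picks the LARGEST optimal threshold at every column, which
// yields the canonical smallest optimal upper set (fewest points high).
//
// [[Rcpp::export(name = ".dp_binary_upper_set")]]
List dp_binary_upper_set(NumericVector x1, NumericVector x2,
                         IntegerVector y, NumericVector w) {
  const int n = x1.size();
  std::vector<double> cols(x1.begin(), x1.end());
  std::sort(cols.begin(), cols.end());
  cols.erase(std::unique(cols.begin(), cols.end()), cols.end());
  const int m = (int)cols.size();

  std::vector<double> th(x2.begin(), x2.end());
  std::sort(th.begin(), th.end());
  th.erase(std::unique(th.begin(), th.end()), th.end());
  const int r = (int)th.size(); // valid threshold indices 0..r, r == +Inf

  std::vector<int> colIdx(n);
  for (int i = 0; i < n; ++i)
    colIdx[i] = (int)(std::lower_bound(cols.begin(), cols.end(), x1[i]) -
                      cols.begin());

  // cost[j][q]: weighted misclassification in column j under threshold q.
  // point i is in the upper set iff th[q] <= x2[i], i.e. q <= pos(i).
  std::vector<std::vector<double>> cost(m, std::vector<double>(r + 1, 0.0));
  for (int i = 0; i < n; ++i) {
    const int j = colIdx[i];
    const int pos = (int)(std::lower_bound(th.begin(), th.end(), x2[i]) -
                          th.begin());
    if (y[i] == 0) {
      for (int q = 0; q <= pos; ++q) cost[j][q] += w[i];
    } else {
      for (int q = pos + 1; q <= r; ++q) cost[j][q] += w[i];
    }
  }

  // Backward DP with prefix minima enforcing q_{j+1} <= q_j.
  std::vector<std::vector<double>> B(m, std::vector<double>(r + 1));
  std::vector<double> pref(r + 1);
  for (int j = m - 1; j >= 0; --j) {
    for (int q = 0; q <= r; ++q)
      B[j][q] = cost[j][q] + (j == m - 1 ? 0.0 : pref[q]);
    pref[0] = B[j][0];
    for (int q = 1; q <= r; ++q) pref[q] = std::min(pref[q - 1], B[j][q]);
  }

  // Greedy-largest reconstruction (smallest optimal upper set).
  std::vector<int> qsel(m);
  int cap = r;
  for (int j = 0; j < m; ++j) {
    double best = B[j][0];
    for (int q = 1; q <= cap; ++q) best = std::min(best, B[j][q]);
    int pick = 0;
    for (int q = cap; q >= 0; --q)
      if (B[j][q] == best) { pick = q; break; }
    qsel[j] = pick;
    cap = pick;
  }

  LogicalVector high(n);
  double err = 0.0;
  for (int i = 0; i < n; ++i) {
    const int q = qsel[colIdx[i]];
    const bool inU = (q < r) && (x2[i] >= th[q]);
    high[i] = inU;
    if (inU != (y[i] == 1)) err += w[i];
  }
  return List::create(_["high"] = high, _["error"] = err);
}
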