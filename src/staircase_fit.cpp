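// Full multi-class staircase fit in one call: orientation search, recursive
// class-range splitting, binary threshold DPs on point subsets, and corner
// geometry. Mirrors the conventions documented in R/staircase.R.
#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <vector>
using namespace Rcpp;

typedef std::pair<double, double> Pt;
typedef std::vector<Pt> Corners;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Pareto minima (antichain) of a corner set, sorted by first coordinate.
static Corners pareto_min(Corners pts) {
  if (pts.empty()) return pts;
  std::sort(pts.begin(), pts.end());
  Corners out;
  double best = std::numeric_limits<double>::infinity();
  for (const Pt& p : pts) {
    if (p.second < best) {
      out.push_back(p);
      best = p.second;
    }
  }
  return out;
}

static bool in_upper(const Corners& c, double x, double y) {
  for (const Pt& q : c)
    if (x >= q.first && y >= q.second) return true;
  return false;
}

// Binary L1-optimal monotone upper set; returns per-point assignment of the
// canonical smallest optimal upper set (greedy-largest thresholds).
static std::vector<char> bin_fit(const std::vector<double>& z1,
                                 const std::vector<double>& z2,
                                 const std::vector<char>& yb,
                                 const std::vector<double>& w) {
  const int n = (int)z1.size();
  std::vector<double> cols(z1);
  std::sort(cols.begin(), cols.end());
  cols.erase(std::unique(cols.begin(), cols.end()), cols.end());
  std::vector<double> th(z2);
  std::sort(th.begin(), th.end());
  th.erase(std::unique(th.begin(), th.end()), th.end());
  const int m = (int)cols.size(), r = (int)th.size();
  const int R = r + 1; // threshold index r == +Inf (column fully below)

  std::vector<int> colIdx(n), pos(n);
  for (int i = 0; i < n; ++i) {
    colIdx[i] = (int)(std::lower_bound(cols.begin(), cols.end(), z1[i]) -
                      cols.begin());
    pos[i] = (int)(std::lower_bound(th.begin(), th.end(), z2[i]) - th.begin());
  }
  std::vector<double> cost((size_t)m * R, 0.0);
  for (int i = 0; i < n; ++i) {
    double* cj = &cost[(size_t)colIdx[i] * R];
    if (!yb[i]) {
      for (int q = 0; q <= pos[i]; ++q) cj[q] += w[i];
    } else {
      for (int q = pos[i] + 1; q < R; ++q) cj[q] += w[i];
    }
  }
  std::vector<double> B((size_t)m * R), pref(R);
  for (int j = m - 1; j >= 0; --j) {
    double* Bj = &B[(size_t)j * R];
    const double* cj = &cost[(size_t)j * R];
    if (j == m - 1) {
      for (int q = 0; q < R; ++q) Bj[q] = cj[q];
    } else {
      for (int q = 0; q < R; ++q) Bj[q] = cj[q] + pref[q];
    }
    pref[0] = Bj[0];
    for (int q = 1; q < R; ++q) pref[q] = std::min(pref[q - 1], Bj[q]);
  }
  std::vector<int> qsel(m);
  int cap = R - 1;
  for (int j = 0; j < m; ++j) {
    const double* Bj = &B[(size_t)j * R];
    double best = Bj[0];
    for (int q = 1; q <= cap; ++q) best = std::min(best, Bj[q]);
    int pick = 0;
    for (int q = cap; q >= 0; --q)
      if (Bj[q] == best) { pick = q; break; }
    qsel[j] = pick;
    cap = pick;
  }
  std::vector<char> high(n);
  for (int i = 0; i < n; ++i) {
    const int q = qsel[colIdx[i]];
    high[i] = (q < r) && (pos[i] >= q);
  }
  return high;
}

// Recursive divide and conquer over class range a..b; returns boundaries for
// thresholds (a+1)..b. `region` is the parent boundary right-side fits are
// constrained to (null at top level and for left-side recursions).
static std::vector<Corners> fit_range(const std::vector<double>& z1,
                                      const std::vector<double>& z2,
                                      const std::vector<int>& y,
                                      const std::vector<double>& w,
                                      int a, int b, const Corners* region) {
  std::vector<Corners> res;
  if (a == b) return res;
  const int n = (int)z1.size();
  const int k = a + (b - a + 1) / 2;
  std::vector<char> yb(n);
  for (int i = 0; i < n; ++i) yb[i] = y[i] >= k;
  std::vector<char> high = bin_fit(z1, z2, yb, w);
  int nh = 0;
  for (char h : high) nh += h;

  Corners Uk;
  if (nh == 0) {
    // empty upper set
  } else if (nh == n) {
    Uk = region ? *region : Corners{{NEG_INF, NEG_INF}};
  } else {
    Corners pts;
    for (int i = 0; i < n; ++i)
      if (high[i]) pts.push_back({z1[i], z2[i]});
    Uk = pareto_min(std::move(pts));
  }

  std::vector<Corners> left, right;
  if (k - 1 > a) {
    if (nh < n) {
      std::vector<double> l1, l2, lw;
      std::vector<int> ly;
      for (int i = 0; i < n; ++i)
        if (!high[i]) {
          l1.push_back(z1[i]); l2.push_back(z2[i]);
          ly.push_back(y[i]); lw.push_back(w[i]);
        }
      left = fit_range(l1, l2, ly, lw, a, k - 1, nullptr);
    } else {
      left.assign(k - 1 - a, Uk); // no low points: whole scope is high
    }
  }
  if (b > k) {
    if (nh > 0) {
      std::vector<double> r1, r2, rw;
      std::vector<int> ry;
      for (int i = 0; i < n; ++i)
        if (high[i]) {
          r1.push_back(z1[i]); r2.push_back(z2[i]);
          ry.push_back(y[i]); rw.push_back(w[i]);
        }
      right = fit_range(r1, r2, ry, rw, k, b, &Uk);
    } else {
      right.assign(b - k, Corners());
    }
  }

  for (Corners& L : left) {
    Corners u = L;
    u.insert(u.end(), Uk.begin(), Uk.end());
    res.push_back(pareto_min(std::move(u)));
  }
  res.push_back(Uk);
  for (Corners& Rb : right) res.push_back(std::move(Rb));
  return res;
}

static int predict_pt(const std::vector<Corners>& bds, double x, double y) {
  int lab = 0;
  for (const Corners& bd : bds)
    if (in_upper(bd, x, y)) ++lab; // nested: higher boundaries are subsets
  return lab;
}

// Fit p-class staircases for each candidate orientation and return the best
// (first minimum in the supplied candidate order).
// [[Rcpp::export(name = ".dp_staircase_multi")]]
List dp_staircase_multi(NumericVector x1, NumericVector x2, IntegerVector y,
                        NumericVector w, int p, IntegerVector cand_s1,
                        IntegerVector cand_s2) {
  const int n = x1.size(), nc = cand_s1.size();
  std::vector<int> yy(y.begin(), y.end());
  std::vector<double> ww(w.begin(), w.end());

  double best_err = std::numeric_limits<double>::infinity();
  int best_c = -1;
  std::vector<Corners> best_bds;

  for (int c = 0; c < nc; ++c) {
    std::vector<double> z1(n), z2(n);
    for (int i = 0; i < n; ++i) {
      z1[i] = cand_s1[c] * x1[i];
      z2[i] = cand_s2[c] * x2[i];
    }
    std::vector<Corners> bds = fit_range(z1, z2, yy, ww, 0, p - 1, nullptr);
    double err = 0.0;
    for (int i = 0; i < n; ++i)
      err += ww[i] * std::abs(predict_pt(bds, z1[i], z2[i]) - yy[i]);
    if (err < best_err) {
      best_err = err;
      best_c = c;
      best_bds = std::move(bds);
    }
  }

  List bout(best_bds.size());
  for (size_t t = 0; t < best_bds.size(); ++t) {
    const Corners& bd = best_bds[t];
    NumericMatrix m((int)bd.size(), 2);
    for (int i = 0; i < (int)bd.size(); ++i) {
      m(i, 0) = bd[i].first;
      m(i, 1) = bd[i].second;
    }
    bout[t] = m;
  }
  return List::create(_["s1"] = cand_s1[best_c], _["s2"] = cand_s2[best_c],
                      _["training_error"] = best_err,
                      _["boundaries"] = bout);
}
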