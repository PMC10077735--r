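#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Adaptive-partitioning mutual information on rank coordinates.
// Points carry integer ranks 1..n on both axes (ties broken upstream by
// deterministic jitter). The unit square in rank space is split recursively
// into quadrants at the midpoint of the current cell; a split is accepted
// when the chi-square statistic of quadrant occupancy exceeds the 5%
// critical value at 1 df (rank margins pin the row/column sums of the
// quadrant table, leaving a single free cell). Each accepted leaf
// contributes
//   n_q/N * log(n_q * N / (dx * dy))
// where dx, dy are the leaf's rank-interval widths (the marginal counts,
// since ranks are uniform).

static const double CHI2_CRIT_1DF_05 = 3.841459;

struct APState {
  const int *x;
  const int *y;
  int n_total;
  double mi;
};

static void ap_recurse(APState &st, std::vector<int> &idx,
                       int x0, int x1, int y0, int y1) {
  const int n = (int)idx.size();
  if (n == 0) return;
  const int dx = x1 - x0 + 1, dy = y1 - y0 + 1;
  bool can_split = (n >= 8) && (dx >= 2) && (dy >= 2);
  if (can_split) {
    int xm = x0 + (dx / 2) - 1;  // left half: [x0, xm]
    int ym = y0 + (dy / 2) - 1;
    std::vector<int> q1, q2, q3, q4;
    q1.reserve(n); q2.reserve(n); q3.reserve(n); q4.reserve(n);
    for (int i = 0; i < n; ++i) {
      int p = idx[i];
      bool left = st.x[p] <= xm, low = st.y[p] <= ym;
      if (left && low) q1.push_back(p);
      else if (left) q2.push_back(p);
      else if (low) q3.push_back(p);
      else q4.push_back(p);
    }
    double e = n / 4.0;
    double chi2 = 0.0;
    chi2 += (q1.size() - e) * (q1.size() - e) / e;
    chi2 += (q2.size() - e) * (q2.size() - e) / e;
    chi2 += (q3.size() - e) * (q3.size() - e) / e;
    chi2 += (q4.size() - e) * (q4.size() - e) / e;
    if (chi2 > CHI2_CRIT_1DF_05) {
      idx.clear(); idx.shrink_to_fit();
      ap_recurse(st, q1, x0, xm, y0, ym);
      ap_recurse(st, q2, x0, xm, ym + 1, y1);
      ap_recurse(st, q3, xm + 1, x1, y0, ym);
      ap_recurse(st, q4, xm + 1, x1, ym + 1, y1);
      return;
    }
  }
  // leaf
  double N = (double)st.n_total;
  st.mi += (n / N) * std::log(n * N / ((double)dx * (double)dy));
}

static double ap_mi_one(const int *xr, const int *yr, int n) {
  // Canonical orientation: reflect y when the rank covariance is negative,
  // so the estimate is invariant to sign flips of either argument (the
  // quadrant split rounds odd widths and is not mirror-symmetric itself).
  double sxy = 0.0;
  for (int i = 0; i < n; ++i) sxy += (double)xr[i] * yr[i];
  double expect = (double)n * (n + 1.0) * (n + 1.0) / 4.0;
  std::vector<int> ybuf;
  const int *yy = yr;
  if (sxy < expect) {
    ybuf.resize(n);
    for (int i = 0; i < n; ++i) ybuf[i] = n + 1 - yr[i];
    yy = ybuf.data();
  }
  APState st;
  st.x = xr; st.y = yy; st.n_total = n; st.mi = 0.0;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  ap_recurse(st, idx, 1, n, 1, n);
  return st.mi > 0.0 ? st.mi : 0.0;
}

// [[Rcpp::export(name = ".ap_mi_pair")]]
double ap_mi_pair(IntegerVector xr, IntegerVector yr) {
  int n = xr.size();
  if (yr.size() != n) stop("rank vectors must have equal length");
  return ap_mi_one(INTEGER(xr), INTEGER(yr), n);
}

// ranks: genes x samples integer matrix of within-row ranks (1..n per row).
// reg_idx: 1-based row indices of regulators.
// Returns a nreg x ngenes matrix of MI values; self pairs are 0.
// [[Rcpp::export(name = ".ap_mi_matrix")]]
NumericMatrix ap_mi_matrix(IntegerMatrix ranks, IntegerVector reg_idx) {
  const int ng = ranks.nrow(), n = ranks.ncol(), nr = reg_idx.size();
  NumericMatrix out(nr, ng);
  // row-major copies for cache-friendly recursion
  std::vector<std::vector<int>> rows(ng, std::vector<int>(n));
  for (int g = 0; g < ng; ++g)
    for (int j = 0; j < n; ++j) rows[g][j] = ranks(g, j);
  for (int r = 0; r < nr; ++r) {
    int gi = reg_idx[r] - 1;
    if (gi < 0 || gi >= ng) stop("regulator index out of range");
    const int *xr = rows[gi].data();
    for (int g = 0; g < ng; ++g) {
      if (g == gi) { out(r, g) = 0.0; continue; }
      out(r, g) = ap_mi_one(xr, rows[g].data(), n);
    }
  }
  return out;
}
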