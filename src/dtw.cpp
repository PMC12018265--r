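#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Band test: cell (i, j) (0-based) is admissible when the deviation from the
// rescaled diagonal |i * m/n - j| does not exceed `band` (in samples of the
// second series). band < 0 disables the constraint.
static inline bool in_band(int i, int j, int n, int m, double band) {
  if (band < 0) return true;
  double diag = (double)i * (double)m / (double)n;
  return std::fabs(diag - (double)j) <= band;
}

// Accumulated DTW distance over a local-cost matrix with the symmetric step
// pattern {(1,0), (0,1), (1,1)}, optionally Sakoe-Chiba banded.
// [[Rcpp::export]]
double dtw_cost_dist(NumericMatrix cost, double band = -1.0) {
  int n = cost.nrow(), m = cost.ncol();
  std::vector<double> prev(m, R_PosInf), cur(m, R_PosInf);
  for (int i = 0; i < n; ++i) {
    std::fill(cur.begin(), cur.end(), R_PosInf);
    for (int j = 0; j < m; ++j) {
      if (!in_band(i, j, n, m, band)) continue;
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = R_PosInf;
        if (i > 0) best = std::min(best, prev[j]);
        if (j > 0) best = std::min(best, cur[j - 1]);
        if (i > 0 && j > 0) best = std::min(best, prev[j - 1]);
        if (!R_FINITE(best)) continue;
      }
      cur[j] = cost(i, j) + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Fill one frequency slab of a (channel x freq x time) amplitude array from
// the decimated modulus matrix A (m2 x channel), linearly interpolated at
// fractional indices posf (0-based). Modifies `amp` in place.
// [[Rcpp::export]]
void cwt_fill(NumericVector amp, NumericMatrix A, NumericVector posf,
              int k, int nch, int nfreq) {
  int n = posf.size();
  int m2 = A.nrow();
  for (int t = 0; t < n; ++t) {
    double p = posf[t];
    int i0 = (int)std::floor(p);
    if (i0 < 0) i0 = 0;
    if (i0 > m2 - 2) i0 = m2 - 2;
    double w = p - i0;
    R_xlen_t base = (R_xlen_t)nch * ((R_xlen_t)k + (R_xlen_t)nfreq * t);
    for (int c = 0; c < nch; ++c) {
      amp[base + c] = A(i0, c) * (1.0 - w) + A(i0 + 1, c) * w;
    }
  }
}

// DTW distance between two 2D point sequences (Euclidean local cost),
// rolling-array DP, no path.
// [[Rcpp::export]]
double dtw_xy_dist(NumericMatrix x, NumericMatrix y) {
  int n = x.nrow(), m = y.nrow();
  std::vector<double> prev(m, R_PosInf), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double dx = x(i, 0) - y(j, 0), dy = x(i, 1) - y(j, 1);
      double c = std::sqrt(dx * dx + dy * dy);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else {
        best = R_PosInf;
        if (i > 0) best = std::min(best, prev[j]);
        if (j > 0) best = std::min(best, cur[j - 1]);
        if (i > 0 && j > 0) best = std::min(best, prev[j - 1]);
      }
      cur[j] = c + best;
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), R_PosInf);
  }
  return prev[m - 1];
}

// Banded DTW between two phase series with squared circular local cost,
// computed on the fly (no cost matrix from R). Same step pattern and band
// convention as dtw_cost_path; returns the distance and 1-based path.
// [[Rcpp::export]]
List dtw_circ_path(NumericVector a, NumericVector b, double band = -1.0) {
  int n = a.size(), m = b.size();
  NumericMatrix D(n, m);
  std::fill(D.begin(), D.end(), R_PosInf);
  const double TWOPI = 2.0 * M_PI;
  for (int i = 0; i < n; ++i) {
    int j0 = 0, j1 = m - 1;
    if (band >= 0) {
      double diag = (double)i * (double)m / (double)n;
      j0 = std::max(0, (int)std::ceil(diag - band));
      j1 = std::min(m - 1, (int)std::floor(diag + band));
    }
    for (int j = j0; j <= j1; ++j) {
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = R_PosInf;
        if (i > 0) best = std::min(best, D(i - 1, j));
        if (j > 0) best = std::min(best, D(i, j - 1));
        if (i > 0 && j > 0) best = std::min(best, D(i - 1, j - 1));
        if (!R_FINITE(best)) continue;
      }
      // inputs are phases in [0, 2*pi), so |a - b| < 2*pi already
      double d = std::fabs(a[i] - b[j]);
      if (d > M_PI) d = TWOPI - d;
      D(i, j) = d * d + best;
    }
  }
  if (!R_FINITE(D(n - 1, m - 1)))
    stop("DTW band too narrow: no admissible path");
  std::vector<int> pi_, pj_;
  int i = n - 1, j = m - 1;
  pi_.push_back(i); pj_.push_back(j);
  while (i > 0 || j > 0) {
    double d_diag = (i > 0 && j > 0) ? D(i - 1, j - 1) : R_PosInf;
    double d_up   = (i > 0) ? D(i - 1, j) : R_PosInf;
    double d_left = (j > 0) ? D(i, j - 1) : R_PosInf;
    if (d_diag <= d_up && d_diag <= d_left) { --i; --j; }
    else if (d_up <= d_left) { --i; }
    else { --j; }
    pi_.push_back(i); pj_.push_back(j);
  }
  int k = (int)pi_.size();
  IntegerMatrix path(k, 2);
  for (int r = 0; r < k; ++r) {
    path(r, 0) = pi_[k - 1 - r] + 1;
    path(r, 1) = pj_[k - 1 - r] + 1;
  }
  return List::create(_["distance"] = D(n - 1, m - 1), _["path"] = path);
}

// Full DTW with path backtracking. Returns the accumulated distance and the
// warping path as a k x 2 matrix of 1-based (row, column) index pairs from
// (1, 1) to (n, m).
// [[Rcpp::export]]
List dtw_cost_path(NumericMatrix cost, double band = -1.0) {
  int n = cost.nrow(), m = cost.ncol();
  NumericMatrix D(n, m);
  std::fill(D.begin(), D.end(), R_PosInf);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (!in_band(i, j, n, m, band)) continue;
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = R_PosInf;
        if (i > 0) best = std::min(best, D(i - 1, j));
        if (j > 0) best = std::min(best, D(i, j - 1));
        if (i > 0 && j > 0) best = std::min(best, D(i - 1, j - 1));
        if (!R_FINITE(best)) continue;
      }
      D(i, j) = cost(i, j) + best;
    }
  }
  if (!R_FINITE(D(n - 1, m - 1)))
    stop("DTW band too narrow: no admissible path");

  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    double d_diag = (i > 0 && j > 0) ? D(i - 1, j - 1) : R_PosInf;
    double d_up   = (i > 0) ? D(i - 1, j) : R_PosInf;
    double d_left = (j > 0) ? D(i, j - 1) : R_PosInf;
    if (d_diag <= d_up && d_diag <= d_left) { --i; --j; }
    else if (d_up <= d_left) { --i; }
    else { --j; }
    pi.push_back(i); pj.push_back(j);
  }
  int k = (int)pi.size();
  IntegerMatrix path(k, 2);
  for (int r = 0; r < k; ++r) {
    path(r, 0) = pi[k - 1 - r] + 1;
    path(r, 1) = pj[k - 1 - r] + 1;
  }
  return List::create(_["distance"] = D(n - 1, m - 1), _["path"] = path);
}
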