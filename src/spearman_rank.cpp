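#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Midranks (average ranks for ties), written into r. buf is a reusable
// (value, index) buffer of length n; sorting packed pairs keeps the
// comparisons cache-local.
static void midranks(const double *x, int n,
                     std::vector<std::pair<double, int>> &buf, double *r) {
  for (int i = 0; i < n; ++i) buf[i] = std::make_pair(x[i], i);
  std::sort(buf.begin(), buf.begin() + n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && buf[j + 1].first == buf[i].first) ++j;
    double avg = (i + j) / 2.0 + 1.0; // 1-based average rank of the tie block
    for (int k = i; k <= j; ++k) r[buf[k].second] = avg;
    i = j + 1;
  }
}

// Spearman rho of every column of X against y: midrank both sides, then
// Pearson on the ranks. Zero-variance columns (or a zero-variance y) give
// rho = 0; the caller assigns p = 1 to those. Returns rho and a logical
// degenerate flag per column.
// [[Rcpp::export(name = ".spearman_rho_matrix")]]
List spearman_rho_matrix(NumericMatrix X, NumericVector y) {
  const int n = X.nrow(), E = X.ncol();
  std::vector<std::pair<double, int>> ord(n);
  std::vector<double> ry(n), rx(n);
  midranks(REAL(y), n, ord, ry.data());
  const double mu = (n + 1) / 2.0; // mean of any midrank vector
  double syy = 0.0;
  for (int i = 0; i < n; ++i) syy += (ry[i] - mu) * (ry[i] - mu);

  NumericVector rho(E);
  LogicalVector degenerate(E);
  for (int j = 0; j < E; ++j) {
    midranks(&X(0, j), n, ord, rx.data());
    double sxx = 0.0, sxy = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dx = rx[i] - mu;
      sxx += dx * dx;
      sxy += dx * (ry[i] - mu);
    }
    if (sxx <= 0.0 || syy <= 0.0) {
      rho[j] = 0.0;
      degenerate[j] = true;
    } else {
      double r = sxy / std::sqrt(sxx * syy);
      rho[j] = std::max(-1.0, std::min(1.0, r));
      degenerate[j] = false;
    }
  }
  return List::create(_["rho"] = rho, _["degenerate"] = degenerate);
}

// Per-column sort orders (0-based), computed once per training matrix so
// that resample screens can rank row subsets by a linear scan instead of a
// fresh sort.
// [[Rcpp::export(name = ".col_order")]]
IntegerMatrix col_order(NumericMatrix X) {
  const int n = X.nrow(), E = X.ncol();
  IntegerMatrix out(n, E);
  std::vector<std::pair<double, int>> buf(n);
  for (int j = 0; j < E; ++j) {
    const double *x = &X(0, j);
    for (int i = 0; i < n; ++i) buf[i] = std::make_pair(x[i], i);
    std::sort(buf.begin(), buf.end());
    for (int i = 0; i < n; ++i) out(i, j) = buf[i].second;
  }
  return out;
}

// Signed significance of the Spearman screen on a resampled subject set,
// one entry per edge: +1 / -1 when |rho| exceeds r_crit (the critical
// correlation for the two-sided t test at the screening level), else 0.
//
// cnt[i] is the multiplicity of subject i in the resample (0/1 for
// subsampling without replacement, >= 0 for the classic bootstrap:
// duplicated subjects are genuine repeated observations and land in one
// midrank tie block). ry[i] is the midrank of y_i within the resampled
// multiset (any value for cnt[i] == 0), m the total number of draws and
// syy the centered sum of squares of the y midranks. Edge ranks come from
// scanning the precomputed sort order, so the per-resample cost is linear
// in the training size.
// [[Rcpp::export(name = ".stability_screen")]]
IntegerVector stability_screen(NumericMatrix X, IntegerMatrix ord,
                               IntegerVector cnt, NumericVector ry,
                               double m, double syy, double r_crit) {
  const int n = X.nrow(), E = X.ncol();
  const double mu = (m + 1) / 2.0;
  IntegerVector out(E);
  for (int j = 0; j < E; ++j) {
    const double *x = &X(0, j);
    const int *o = &ord(0, j);
    double sxx = 0.0, sxy = 0.0, pos = 1.0;
    int i = 0;
    while (i < n) {
      const int oi = o[i];
      const double v = x[oi];
      if (i + 1 == n || x[o[i + 1]] != v) {
        // unique value: its multiplicity (if any) is one tie block
        const int c = cnt[oi];
        if (c) {
          const double dx = pos + (c - 1) / 2.0 - mu; // centered midrank
          sxy += c * dx * (ry[oi] - mu);
          sxx += c * dx * dx;
          pos += c;
        }
        ++i;
      } else {
        int k = i;
        double W = 0.0; // selected multiplicity of this tie block
        while (k < n && x[o[k]] == v) { W += cnt[o[k]]; ++k; }
        if (W > 0.0) {
          const double dx = pos + (W - 1) / 2.0 - mu;
          for (int t = i; t < k; ++t) {
            const int c = cnt[o[t]];
            if (c) sxy += c * dx * (ry[o[t]] - mu);
          }
          sxx += W * dx * dx;
          pos += W;
        }
        i = k;
      }
    }
    if (sxx <= 0.0 || syy <= 0.0) { out[j] = 0; continue; }
    const double rho = sxy / std::sqrt(sxx * syy);
    out[j] = (std::fabs(rho) > r_crit) ? (rho > 0 ? 1 : -1) : 0;
  }
  return out;
}
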