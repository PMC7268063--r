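#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dual coordinate descent for linear epsilon-insensitive SVR
// (the liblinear algorithm for L1-loss SVR):
//
//   min_w  0.5 * ||w||^2 + C * sum_i max(0, |w.x_i - y_i| - eps)
//
// solved through its dual in beta_i in [-C, C],
//   min 0.5 * beta' Q beta - y' beta + eps * ||beta||_1,  Q = X X',
// maintaining w = sum_i beta_i x_i. An intercept, when wanted, is supplied
// by the caller as an appended constant column (it then carries a 0.5*b^2
// term; negligible when the target is centered). Coordinates are visited in
// a deterministically shuffled order (internal LCG), so fits are
// bit-reproducible. An epoch's maximal projected-gradient violation below
// tol stops the solve.
//
// The exported entry solves a whole ascending C path with warm starts: the
// dual solution at one C is feasible for the next (bounds only widen), so
// later grid points converge in a handful of epochs. This is what makes the
// 16-point C grid affordable inside nested cross-validation.

struct DcdState {
  std::vector<double> Xr; // row-major copy of X
  std::vector<double> beta, w, QD;
  int n, p;
  unsigned long long lcg = 88172645463325252ULL;
};

static void dcd_init(DcdState &st, const NumericMatrix &X) {
  st.n = X.nrow();
  st.p = X.ncol();
  st.Xr.resize(static_cast<size_t>(st.n) * st.p);
  for (int i = 0; i < st.n; ++i)
    for (int j = 0; j < st.p; ++j)
      st.Xr[static_cast<size_t>(i) * st.p + j] = X(i, j);
  st.beta.assign(st.n, 0.0);
  st.w.assign(st.p, 0.0);
  st.QD.resize(st.n);
  for (int i = 0; i < st.n; ++i) {
    double s = 0.0;
    const double *xi = &st.Xr[static_cast<size_t>(i) * st.p];
    for (int j = 0; j < st.p; ++j) s += xi[j] * xi[j];
    st.QD[i] = s;
  }
}

// One solve at a fixed C, warm-started from st.beta/st.w.
// Returns iterations used (max_iter + 1 if not converged).
static int dcd_solve(DcdState &st, const double *y, double C,
                     double eps_tube, double tol, int max_iter) {
  const int n = st.n, p = st.p;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  int iter;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int i = n - 1; i > 0; --i) { // deterministic Fisher-Yates
      st.lcg = st.lcg * 6364136223846793005ULL + 1442695040888963407ULL;
      int j = static_cast<int>((st.lcg >> 33) % static_cast<unsigned>(i + 1));
      std::swap(order[i], order[j]);
    }
    double max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      const int i = order[k];
      if (st.QD[i] <= 0.0) continue; // all-zero sample carries nothing
      const double *xi = &st.Xr[static_cast<size_t>(i) * p];
      double G = -y[i];
      for (int j = 0; j < p; ++j) G += st.w[j] * xi[j];
      const double Gp = G + eps_tube, Gn = G - eps_tube;

      // projected-gradient violation at the current beta_i
      const double b = st.beta[i];
      double viol;
      if (b >= C)        viol = std::max(Gp, 0.0);  // may only decrease
      else if (b <= -C)  viol = std::max(-Gn, 0.0); // may only increase
      else if (b > 0.0)  viol = std::fabs(Gp);
      else if (b < 0.0)  viol = std::fabs(Gn);
      else               viol = std::max(std::max(-Gp, Gn), 0.0);
      if (viol > max_viol) max_viol = viol;

      // Newton step on the piecewise-quadratic coordinate objective
      double d;
      if (Gp < st.QD[i] * b)      d = -Gp / st.QD[i];
      else if (Gn > st.QD[i] * b) d = -Gn / st.QD[i];
      else                        d = -b;
      double nb = std::min(std::max(b + d, -C), C);
      d = nb - b;
      if (std::fabs(d) > 1e-14) {
        for (int j = 0; j < p; ++j) st.w[j] += d * xi[j];
        st.beta[i] = nb;
      }
    }
    if (max_viol < tol) return iter + 1;
  }
  return max_iter + 1;
}

// [[Rcpp::export(name = ".svr_dual_cd_path")]]
List svr_dual_cd_path(NumericMatrix X, NumericVector y, NumericVector Cs,
                      double eps_tube, double tol = 1e-3,
                      int max_iter = 1000) {
  const int nC = Cs.size();
  for (int c = 1; c < nC; ++c)
    if (Cs[c] < Cs[c - 1]) stop("Cs must be ascending for warm starts");
  DcdState st;
  dcd_init(st, X);
  NumericMatrix W(X.ncol(), nC);
  IntegerVector iters(nC);
  LogicalVector converged(nC);
  for (int c = 0; c < nC; ++c) {
    int it = dcd_solve(st, REAL(y), Cs[c], eps_tube, tol, max_iter);
    iters[c] = std::min(it, max_iter);
    converged[c] = it <= max_iter;
    for (int j = 0; j < st.p; ++j) W(j, c) = st.w[j];
  }
  return List::create(_["w"] = W, _["iterations"] = iters,
                      _["converged"] = converged);
}
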