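// Penalized Cox regression for counting-process (start, stop] data.
//
// L1-penalized proportional-hazards fitting along a decreasing lambda
// grid, used by the stability-selection module where thousands of
// moderate-sized penalized fits are needed. Outer loop: iteratively
// reweighted least squares on the Breslow partial likelihood (ties
// handled by the Breslow approximation, standard for penalized Cox
// screening); inner loop: cyclic coordinate descent with an active-set
// strategy on a column-sparse design. The counting-process risk-set
// structure (who is at risk at each event time) is resolved once by
// sorting and binary search; every IRLS pass after that is O(n).
//
// Columns are expected pre-scaled (unit variance) by the caller so the
// penalty is exchangeable across columns.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List lasso_cox_path_cpp(S4 X, NumericVector start, NumericVector stop,
                        IntegerVector event, int nlambda,
                        double lambda_min_ratio, int max_active,
                        int n_irls, double tol, int max_cd) {
  IntegerVector Xi = X.slot("i");
  IntegerVector Xp = X.slot("p");
  NumericVector Xx = X.slot("x");
  IntegerVector dim = X.slot("Dim");
  const int n = dim[0], p = dim[1];

  // distinct event times with multiplicities
  std::vector<double> et;
  for (int i = 0; i < n; ++i) if (event[i]) et.push_back(stop[i]);
  std::sort(et.begin(), et.end());
  std::vector<double> ut;   // unique event times
  std::vector<int> dcount;  // deaths per unique time
  for (size_t k = 0; k < et.size(); ++k) {
    if (ut.empty() || et[k] != ut.back()) { ut.push_back(et[k]); dcount.push_back(1); }
    else ++dcount.back();
  }
  const int E = (int)ut.size();
  if (E == 0) stop("no events");

  // sort intervals by start and by stop (for risk-set sums)
  std::vector<int> ord_start(n), ord_stop(n);
  for (int i = 0; i < n; ++i) ord_start[i] = ord_stop[i] = i;
  std::sort(ord_start.begin(), ord_start.end(),
            [&](int a, int b) { return start[a] < start[b]; });
  std::sort(ord_stop.begin(), ord_stop.end(),
            [&](int a, int b) { return stop[a] < stop[b]; });

  // per event time: how many sorted starts/stops are < t_e
  std::vector<int> a_e(E), b_e(E);
  {
    std::vector<double> ss(n), tt(n);
    for (int i = 0; i < n; ++i) { ss[i] = start[ord_start[i]]; tt[i] = stop[ord_stop[i]]; }
    for (int e = 0; e < E; ++e) {
      a_e[e] = (int)(std::lower_bound(ss.begin(), ss.end(), ut[e]) - ss.begin());
      b_e[e] = (int)(std::lower_bound(tt.begin(), tt.end(), ut[e]) - tt.begin());
    }
  }
  // per interval: number of event times <= start_i / <= stop_i
  std::vector<int> lo(n), hi(n);
  for (int i = 0; i < n; ++i) {
    lo[i] = (int)(std::upper_bound(ut.begin(), ut.end(), start[i]) - ut.begin());
    hi[i] = (int)(std::upper_bound(ut.begin(), ut.end(), stop[i]) - ut.begin());
  }

  std::vector<double> eta(n, 0.0), r(n), g(n), w(n), u(n);
  std::vector<double> cs_start(n + 1), cs_stop(n + 1), cum1(E + 1), cum2(E + 1);
  std::vector<double> beta(p, 0.0), xw2(p, 0.0);
  std::vector<double> f(n, 0.0); // = X beta

  // recompute gradient/curvature of the Breslow log partial likelihood
  // w.r.t. eta, plus the working response products u = w*z = w*eta + g
  auto irls_weights = [&]() {
    for (int i = 0; i < n; ++i) {
      double e = eta[i];
      if (e > 30) e = 30; else if (e < -30) e = -30;
      r[i] = std::exp(e);
    }
    cs_start[0] = cs_stop[0] = 0.0;
    for (int i = 0; i < n; ++i) {
      cs_start[i + 1] = cs_start[i] + r[ord_start[i]];
      cs_stop[i + 1] = cs_stop[i] + r[ord_stop[i]];
    }
    cum1[0] = cum2[0] = 0.0;
    for (int e = 0; e < E; ++e) {
      double S0 = cs_start[a_e[e]] - cs_stop[b_e[e]];
      if (S0 < 1e-300) S0 = 1e-300;
      cum1[e + 1] = cum1[e] + dcount[e] / S0;
      cum2[e + 1] = cum2[e] + dcount[e] / (S0 * S0);
    }
    for (int i = 0; i < n; ++i) {
      double A = cum1[hi[i]] - cum1[lo[i]];
      double B = cum2[hi[i]] - cum2[lo[i]];
      g[i] = (event[i] ? 1.0 : 0.0) - r[i] * A;
      double wi = r[i] * A - r[i] * r[i] * B;
      if (wi < 1e-9) wi = 1e-9;
      w[i] = wi;
      u[i] = wi * eta[i] + g[i];
    }
    // column curvatures (1/n) sum w x^2
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int k = Xp[j]; k < Xp[j + 1]; ++k) s += w[Xi[k]] * Xx[k] * Xx[k];
      xw2[j] = s / n;
    }
  };

  // one coordinate-descent sweep over the given columns; returns max |delta|
  auto cd_sweep = [&](const std::vector<int>& cols, double lambda) {
    double maxd = 0.0;
    for (int j : cols) {
      if (xw2[j] <= 0) continue;
      double xu = 0.0, xwf = 0.0;
      for (int k = Xp[j]; k < Xp[j + 1]; ++k) {
        int i = Xi[k];
        xu += Xx[k] * u[i];
        xwf += w[i] * Xx[k] * f[i];
      }
      double rho = (xu - xwf) / n + xw2[j] * beta[j];
      double bnew = soft(rho, lambda) / xw2[j];
      double d = bnew - beta[j];
      if (d != 0.0) {
        for (int k = Xp[j]; k < Xp[j + 1]; ++k) f[Xi[k]] += d * Xx[k];
        beta[j] = bnew;
        double ad = std::fabs(d);
        if (ad > maxd) maxd = ad;
      }
    }
    return maxd;
  };

  std::vector<int> all_cols(p);
  for (int j = 0; j < p; ++j) all_cols[j] = j;

  // lambda_max from the null gradient
  irls_weights();
  double lmax = 0.0;
  for (int j = 0; j < p; ++j) {
    double xu = 0.0;
    for (int k = Xp[j]; k < Xp[j + 1]; ++k) xu += Xx[k] * u[Xi[k]];
    double a = std::fabs(xu) / n;
    if (a > lmax) lmax = a;
  }
  if (lmax <= 0) lmax = 1e-3;
  NumericVector lambda(nlambda);
  double lfac = std::pow(lambda_min_ratio, 1.0 / (nlambda - 1));
  lambda[0] = lmax;
  for (int k = 1; k < nlambda; ++k) lambda[k] = lambda[k - 1] * lfac;

  NumericMatrix betas(p, nlambda);
  LogicalVector ever(p, false);
  int used = 0;
  for (int k = 0; k < nlambda; ++k) {
    double lam = lambda[k];
    for (int it = 0; it < n_irls; ++it) {
      for (int i = 0; i < n; ++i) eta[i] = f[i];
      irls_weights();
      cd_sweep(all_cols, lam); // full pass may activate new columns
      std::vector<int> active;
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
      for (int cd = 0; cd < max_cd; ++cd)
        if (cd_sweep(active, lam) < tol) break;
    }
    int nact = 0;
    for (int j = 0; j < p; ++j) {
      betas(j, k) = beta[j];
      if (beta[j] != 0.0) { ever[j] = true; ++nact; }
    }
    used = k + 1;
    if (max_active > 0 && nact > max_active) break; // path truncated
  }

  return List::create(_["lambda"] = lambda, _["beta"] = betas,
                      _["ever_active"] = ever, _["nlambda_used"] = used);
}
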