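// Inner event loop of the synthetic registry generator.
//
// Per subject: competing exponential clocks for disease onsets between
// portfolio-change points, and a death time drawn from the
// piecewise-constant baseline hazard scaled by exp(linear predictor of
// the current portfolio and the subject's intrinsic variables). Uses the
// R RNG stream, so results are reproducible under set.seed() and
// byte-identical across the R and compiled paths of a given version.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// time at which the integral from t0 of the piecewise-constant rate
// reaches target (Inf if never)
static double pc_quantile(const NumericVector& times, const NumericVector& rates,
                          double t0, double target) {
  int k = times.size(), seg = 0;
  while (seg + 1 < k && times[seg + 1] <= t0) ++seg;
  double t = t0, acc = target;
  for (;;) {
    double upper = (seg + 1 < k) ? times[seg + 1] : R_PosInf;
    double r = rates[seg];
    if (r > 0) {
      double dt = acc / r;
      if (t + dt <= upper) return t + dt;
      acc -= r * (upper - t);
    }
    if (!R_FINITE(upper)) return R_PosInf;
    t = upper;
    ++seg;
  }
}

// [[Rcpp::export]]
List simulate_core_cpp(int n, NumericVector onset_rate,
                       NumericVector pre_hd_prob, double pre_window,
                       NumericVector base_t, NumericVector base_r,
                       double emigration_rate, NumericVector follow_limit,
                       NumericVector t_beta, List t_dis,
                       NumericMatrix ip) {
  const int nd = onset_rate.size();
  const int nterm = t_beta.size();
  std::vector<std::vector<int> > dis_idx(nterm);
  for (int t = 0; t < nterm; ++t) {
    IntegerVector v = t_dis[t];
    dis_idx[t].assign(v.begin(), v.end()); // 0-based disease indices
  }

  NumericVector end_time(n);
  IntegerVector status(n); // 0 censored, 1 death, 2 emigration
  std::vector<int> ev_pid, ev_dis;
  std::vector<double> ev_time;
  std::vector<char> state(nd);
  std::vector<double> onset_t(nd);

  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < nd; ++d) {
      state[d] = (onset_rate[d] > 0) && (unif_rand() < pre_hd_prob[d]);
      onset_t[d] = state[d] ? -unif_rand() * pre_window : NA_REAL;
    }
    double emig = emigration_rate > 0 ? exp_rand() / emigration_rate : R_PosInf;
    double limit = std::min(follow_limit[i], emig);
    double t = 0.0, end_t;
    int st;
    for (;;) {
      double lp = 0.0;
      for (int k = 0; k < nterm; ++k) {
        double prod = ip(i, k);
        if (prod == 0.0) continue;
        for (size_t m = 0; m < dis_idx[k].size(); ++m)
          if (!state[dis_idx[k][m]]) { prod = 0.0; break; }
        lp += t_beta[k] * prod;
      }
      double death = pc_quantile(base_t, base_r, t,
                                 exp_rand() * std::exp(-lp));
      double t_on = R_PosInf;
      int j = -1;
      for (int d = 0; d < nd; ++d) {
        if (state[d] || onset_rate[d] <= 0) continue;
        double cand = t + exp_rand() / onset_rate[d];
        if (cand < t_on) { t_on = cand; j = d; }
      }
      if (death <= std::min(t_on, limit)) { end_t = death; st = 1; break; }
      if (t_on <= limit) {
        state[j] = 1;
        onset_t[j] = t_on;
        t = t_on;
      } else {
        end_t = limit;
        st = (emig <= follow_limit[i]) ? 2 : 0;
        break;
      }
    }
    end_time[i] = end_t;
    status[i] = st;
    for (int d = 0; d < nd; ++d)
      if (!ISNA(onset_t[d])) {
        ev_pid.push_back(i + 1);
        ev_dis.push_back(d + 1);
        ev_time.push_back(onset_t[d]);
      }
  }
  return List::create(_["end_time"] = end_time, _["status"] = status,
                      _["ev_pid"] = wrap(ev_pid), _["ev_dis"] = wrap(ev_dis),
                      _["ev_time"] = wrap(ev_time));
}
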