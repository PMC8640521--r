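#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// mean firing rate: 0 below threshold, tanh(2(x-theta)/3) above.
static inline double gfun(double x, double theta) {
  return (x > theta) ? std::tanh((x - theta) * (2.0 / 3.0)) : 0.0;
}

// Fixed-step explicit Euler integration of the column dynamics:
//   tau_m u' = -u + W_ee (q o g(u)) - W_ei g_inh + i_aff
//   tau_m v' = -v + W_ie r
//        q'  = -q g(u)/tau_o + (1 - q)/tau_rec
// where r = q o g(u) is the depressed presynaptic rate shared by all
// connections leaving a column (r = g(u) when depress_ie is false), and
// g_inh = g(v), optionally depressed (q o g(v)).  q is clipped to
// [0, 1] after each step as a numerical guard.  The MEG proxy is recorded
// at every step as sum_j megw[j] * q_j * g(u_j), where megw aggregates the
// class-weighted W_ee weights of each presynaptic column (see R side).
//
// Sparse matrices arrive as triplets with 0-based unit indices.  Stimulus
// events arrive sorted by onset; each is a rectangular tone with linear
// on/off ramps of `ramp` ms delivered to one MGN unit.
// [[Rcpp::export]]
List simulate_cpp(IntegerVector ee_pre, IntegerVector ee_post,
                  NumericVector ee_w,
                  IntegerVector ie_pre, IntegerVector ie_post,
                  NumericVector ie_w,
                  NumericVector wei, NumericVector megw,
                  NumericVector tau_o, double tau_m, double theta,
                  double tau_rec, double dt,
                  bool depress_inh, bool depress_ie, bool stsd,
                  NumericVector ev_onset, NumericVector ev_dur,
                  NumericVector ev_amp, IntegerVector ev_unit,
                  double ramp,
                  int n_steps, int record_from, bool record_state,
                  NumericVector u0, NumericVector v0, NumericVector q0) {
  const int n = u0.size();
  const int n_ee = ee_pre.size();
  const int n_ie = ie_pre.size();
  const int n_ev = ev_onset.size();
  const int n_rec = n_steps - record_from;
  if (n_rec < 0) stop("record_from exceeds n_steps");

  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> q(q0.begin(), q0.end());
  std::vector<double> gu(n), r(n), exc(n), vin(n), iaff(n);

  NumericVector meg(n_rec);
  NumericMatrix urec, vrec, qrec, irec;
  if (record_state) {
    urec = NumericMatrix(n_rec, n);
    vrec = NumericMatrix(n_rec, n);
    qrec = NumericMatrix(n_rec, n);
    irec = NumericMatrix(n_rec, n);
  }

  double qmin = 1.0, qmax = 0.0, gmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (q[i] < qmin) qmin = q[i];
    if (q[i] > qmax) qmax = q[i];
  }

  // CSR by presynaptic column: silent columns (rate 0) are skipped in the
  // per-step sweeps, which is where most of the integration time goes.
  std::vector<int> ee_off(n + 1, 0), ee_col(n_ee);
  std::vector<double> ee_val(n_ee);
  for (int j = 0; j < n_ee; ++j) ++ee_off[ee_pre[j] + 1];
  for (int i = 0; i < n; ++i) ee_off[i + 1] += ee_off[i];
  {
    std::vector<int> cur(ee_off.begin(), ee_off.end() - 1);
    for (int j = 0; j < n_ee; ++j) {
      int k = cur[ee_pre[j]]++;
      ee_col[k] = ee_post[j];
      ee_val[k] = ee_w[j];
    }
  }
  std::vector<int> ie_off(n + 1, 0), ie_col(n_ie);
  std::vector<double> ie_val(n_ie);
  for (int j = 0; j < n_ie; ++j) ++ie_off[ie_pre[j] + 1];
  for (int i = 0; i < n; ++i) ie_off[i + 1] += ie_off[i];
  {
    std::vector<int> cur(ie_off.begin(), ie_off.end() - 1);
    for (int j = 0; j < n_ie; ++j) {
      int k = cur[ie_pre[j]]++;
      ie_col[k] = ie_post[j];
      ie_val[k] = ie_w[j];
    }
  }

  int ev_next = 0;
  std::vector<int> active;
  active.reserve(8);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // afferent input from active tone events
    std::fill(iaff.begin(), iaff.end(), 0.0);
    while (ev_next < n_ev && ev_onset[ev_next] <= t) {
      active.push_back(ev_next);
      ++ev_next;
    }
    for (size_t a = 0; a < active.size();) {
      const int e = active[a];
      const double s = t - ev_onset[e];
      if (s >= ev_dur[e]) {
        active[a] = active.back();
        active.pop_back();
        continue;
      }
      double env = 1.0;
      if (ramp > 0) {
        env = std::min(s / ramp, (ev_dur[e] - s) / ramp);
        if (env > 1.0) env = 1.0;
        if (env < 0.0) env = 0.0;
      }
      iaff[ev_unit[e]] += ev_amp[e] * env;
      ++a;
    }

    // rates and depressed presynaptic drive
    for (int i = 0; i < n; ++i) {
      gu[i] = gfun(u[i], theta);
      if (gu[i] > gmax) gmax = gu[i];
      r[i] = stsd ? q[i] * gu[i] : gu[i];
    }

    // record (state and MEG proxy refer to the current state)
    if (step >= record_from) {
      const int k = step - record_from;
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += megw[i] * r[i];
      meg[k] = m;
      if (record_state) {
        for (int i = 0; i < n; ++i) {
          urec(k, i) = u[i];
          vrec(k, i) = v[i];
          qrec(k, i) = q[i];
          irec(k, i) = iaff[i];
        }
      }
    }

    // synaptic input sums (skip silent presynaptic columns)
    std::fill(exc.begin(), exc.end(), 0.0);
    std::fill(vin.begin(), vin.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      if (gu[i] == 0.0) continue;
      const double ri = r[i];
      for (int k = ee_off[i]; k < ee_off[i + 1]; ++k)
        exc[ee_col[k]] += ee_val[k] * ri;
      const double gi = depress_ie ? ri : gu[i];
      for (int k = ie_off[i]; k < ie_off[i + 1]; ++k)
        vin[ie_col[k]] += ie_val[k] * gi;
    }

    // Euler update
    for (int i = 0; i < n; ++i) {
      double gv = gfun(v[i], theta);
      double ginh = depress_inh && stsd ? q[i] * gv : gv;
      double du = (-u[i] + exc[i] - wei[i] * ginh + iaff[i]) / tau_m;
      double dv = (-v[i] + vin[i]) / tau_m;
      u[i] += dt * du;
      v[i] += dt * dv;
      if (stsd) {
        double dq = -q[i] * gu[i] / tau_o[i] + (1.0 - q[i]) / tau_rec;
        q[i] += dt * dq;
        if (q[i] < 0.0) q[i] = 0.0;
        if (q[i] > 1.0) q[i] = 1.0;
        if (q[i] < qmin) qmin = q[i];
        if (q[i] > qmax) qmax = q[i];
      }
      if (!std::isfinite(u[i]) || !std::isfinite(v[i]))
        stop("non-finite state at unit %d, t = %.1f ms", i + 1,
             (step + 1) * dt);
    }
  }

  List out = List::create(
    _["meg"] = meg,
    _["q_min"] = qmin, _["q_max"] = qmax, _["g_max"] = gmax,
    _["u_final"] = NumericVector(u.begin(), u.end()),
    _["v_final"] = NumericVector(v.begin(), v.end()),
    _["q_final"] = NumericVector(q.begin(), q.end()));
  if (record_state) {
    out["u"] = urec;
    out["v"] = vrec;
    out["q"] = qrec;
    out["input"] = irec;
  }
  return out;
}
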