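// Backward-Euler integrator for the discretized ball-and-stick cable with a
// single point sodium conductance, plus tridiagonal and spike-triggered
// average helpers. Internal unit system: mV, ms, nA, uS, nF, um.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Prefactored Thomas algorithm for repeated solves with a fixed tridiagonal
// matrix. low[i] = A(i,i-1) (low[0] unused), up[i] = A(i,i+1) (up[n-1] unused).
struct TriFactor {
  int n;
  std::vector<double> low, cp, denom;
};

TriFactor tri_factor(const std::vector<double>& low,
                     const std::vector<double>& diag,
                     const std::vector<double>& up) {
  int n = (int)diag.size();
  TriFactor f;
  f.n = n;
  f.low = low;
  f.cp.assign(n, 0.0);
  f.denom.assign(n, 0.0);
  f.denom[0] = 1.0 / diag[0];
  if (n > 1) f.cp[0] = up[0] * f.denom[0];
  for (int i = 1; i < n; ++i) {
    double piv = diag[i] - low[i] * f.cp[i - 1];
    f.denom[i] = 1.0 / piv;
    if (i < n - 1) f.cp[i] = up[i] * f.denom[i];
  }
  return f;
}

inline void tri_solve(const TriFactor& f, const double* d, double* y) {
  int n = f.n;
  y[0] = d[0] * f.denom[0];
  for (int i = 1; i < n; ++i)
    y[i] = (d[i] - f.low[i] * y[i - 1]) * f.denom[i];
  for (int i = n - 2; i >= 0; --i)
    y[i] -= f.cp[i] * y[i + 1];
}

inline double boltzmann(double v, double v12, double ka) {
  return 1.0 / (1.0 + std::exp((v12 - v) / ka));
}

}  // namespace

// One-off solve of a general tridiagonal system.
// [[Rcpp::export]]
NumericVector cpp_tridiag_solve(NumericVector low, NumericVector diag,
                                NumericVector up, NumericVector rhs) {
  int n = diag.size();
  std::vector<double> l(low.begin(), low.end());
  std::vector<double> d(diag.begin(), diag.end());
  std::vector<double> u(up.begin(), up.end());
  TriFactor f = tri_factor(l, d, u);
  NumericVector out(n);
  tri_solve(f, &rhs[0], &out[0]);
  return out;
}

// Integrate the discretized cell. Voltages advance by an implicit (backward
// Euler) tridiagonal solve; the gating variable m relaxes exponentially toward
// m_inf(V_na) over dt using the pre-step axonal voltage, and the sodium
// conductance gbar*m is held at its updated value, implicit in voltage, via a
// Sherman-Morrison rank-1 correction to the prefactored passive system.
//
// clamp_node >= 0 turns that node into a Dirichlet boundary; clamp_vals may be
// length 1 (constant) or n_steps (per-step trajectory).
// [[Rcpp::export]]
List cpp_simulate(NumericVector cap, NumericVector gleak, NumericVector gax,
                  double e_leak, int inj_node, int na_node, double gbar,
                  double e_na, double v_half, double k_a, double tau_m,
                  NumericVector stim, double dt, double detect_thr,
                  double reset_thr, double reset_v, double m_reset,
                  bool do_reset, bool do_detect, bool stop_at_detect,
                  NumericVector v0, double m0, IntegerVector record_nodes,
                  int record_every, double relax_tol, int clamp_node,
                  NumericVector clamp_vals) {
  const int n = cap.size();
  const int n_steps = stim.size();
  const bool clamped = clamp_node >= 0;

  // Assemble the constant passive backward-Euler matrix A0 = C/dt + G.
  std::vector<double> low(n, 0.0), diag(n, 0.0), up(n, 0.0);
  for (int i = 0; i < n; ++i) diag[i] = cap[i] / dt + gleak[i];
  for (int i = 0; i < n - 1; ++i) {
    diag[i] += gax[i];
    diag[i + 1] += gax[i];
    up[i] = -gax[i];
    low[i + 1] = -gax[i];
  }
  if (clamped) {
    diag[clamp_node] = 1.0;
    if (clamp_node > 0) low[clamp_node] = 0.0;
    if (clamp_node < n - 1) up[clamp_node] = 0.0;
  }
  TriFactor f = tri_factor(low, diag, up);

  // z = A0^{-1} e_na for the sodium rank-1 update.
  std::vector<double> z(n), rhs(n), y(n);
  std::fill(rhs.begin(), rhs.end(), 0.0);
  rhs[na_node] = 1.0;
  tri_solve(f, rhs.data(), z.data());

  std::vector<double> v(v0.begin(), v0.end());
  double m = m0;
  const double edt = std::exp(-dt / tau_m);

  // Hoisted per-step invariants.
  std::vector<double> cap_dt(n), leak_el(n);
  for (int i = 0; i < n; ++i) {
    cap_dt[i] = cap[i] / dt;
    leak_el[i] = gleak[i] * e_leak;
  }
  const bool clamp_const = clamp_vals.size() == 1;
  const double* stim_p = &stim[0];
  const bool track_relax = relax_tol > 0.0;

  // Recording buffers.
  const int n_rec_nodes = record_nodes.size();
  int n_rec = 0;
  if (record_every > 0) n_rec = n_steps / record_every + 1;
  NumericMatrix rec(n_rec, n_rec_nodes);
  NumericVector rec_t(n_rec);
  int rec_i = 0;
  if (record_every > 0) {
    for (int j = 0; j < n_rec_nodes; ++j) rec(0, j) = v[record_nodes[j]];
    rec_t[0] = 0.0;
    rec_i = 1;
  }

  std::vector<double> spikes, latencies;
  bool armed = true;
  double t_last_detect = NA_REAL;
  bool converged = false;
  int steps_done = 0;

  for (int k = 0; k < n_steps; ++k) {
    double v_na_old = v[na_node];
    // Staggered gating update (exact exponential relaxation).
    double minf = boltzmann(v_na_old, v_half, k_a);
    m = minf + (m - minf) * edt;
    double g_na = gbar * m;

    for (int i = 0; i < n; ++i) rhs[i] = cap_dt[i] * v[i] + leak_el[i];
    rhs[inj_node] += stim_p[k];
    rhs[na_node] += g_na * e_na;
    if (clamped) {
      double cv = clamp_const ? clamp_vals[0] : clamp_vals[k];
      rhs[clamp_node] = cv;
    }
    tri_solve(f, rhs.data(), y.data());
    double corr = 0.0;
    if (g_na > 0.0) corr = g_na * y[na_node] / (1.0 + g_na * z[na_node]);

    double max_dv = 0.0;
    if (track_relax) {
      for (int i = 0; i < n; ++i) {
        double vn = y[i] - corr * z[i];
        double d = std::fabs(vn - v[i]);
        if (d > max_dv) max_dv = d;
        v[i] = vn;
      }
    } else {
      for (int i = 0; i < n; ++i) v[i] = y[i] - corr * z[i];
    }
    double t_new = (k + 1) * dt;
    double v_na_new = v[na_node];

    bool stop = false;
    if (do_detect && armed && v_na_old < detect_thr && v_na_new >= detect_thr) {
      double frac = (detect_thr - v_na_old) / (v_na_new - v_na_old);
      t_last_detect = k * dt + frac * dt;
      spikes.push_back(t_last_detect);
      if (do_reset) armed = false;
      if (stop_at_detect) stop = true;
    }
    if (do_detect && !do_reset && !armed && v_na_new < detect_thr) armed = true;

    if (do_reset && v_na_old < reset_thr && v_na_new >= reset_thr) {
      double frac = (reset_thr - v_na_old) / (v_na_new - v_na_old);
      if (R_finite(t_last_detect))
        latencies.push_back(k * dt + frac * dt - t_last_detect);
      for (int i = 0; i < n; ++i) v[i] = reset_v;
      if (clamped) {
        double cv = clamp_vals.size() == 1 ? clamp_vals[0] : clamp_vals[k];
        v[clamp_node] = cv;
      }
      m = m_reset;
      armed = true;
      t_last_detect = NA_REAL;
    }

    steps_done = k + 1;
    if (record_every > 0 && (k + 1) % record_every == 0 && rec_i < n_rec) {
      for (int j = 0; j < n_rec_nodes; ++j) rec(rec_i, j) = v[record_nodes[j]];
      rec_t[rec_i] = t_new;
      ++rec_i;
    }
    if (stop) break;
    if (relax_tol > 0.0 && max_dv / dt < relax_tol) {
      converged = true;
      break;
    }
  }

  if (record_every > 0 && rec_i < n_rec) {
    rec = rec(Range(0, rec_i - 1), Range(0, n_rec_nodes - 1));
    rec_t = rec_t[Range(0, rec_i - 1)];
  }

  return List::create(
      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()),
      _["latencies"] = NumericVector(latencies.begin(), latencies.end()),
      _["rec"] = rec, _["rec_t"] = rec_t,
      _["v"] = NumericVector(v.begin(), v.end()), _["m"] = m,
      _["steps_done"] = steps_done, _["converged"] = converged);
}

// Accumulate spike-triggered windows of x (one trial). spk_idx are 0-based
// sample indices; windows clipped at trial edges are excluded.
// [[Rcpp::export]]
List cpp_sta_accumulate(NumericVector x, IntegerVector spk_idx, int halfw) {
  int n = x.size(), w = 2 * halfw + 1;
  NumericVector acc(w);
  int used = 0;
  for (int s = 0; s < spk_idx.size(); ++s) {
    int c = spk_idx[s];
    if (c - halfw < 0 || c + halfw >= n) continue;
    const double* xp = &x[c - halfw];
    for (int j = 0; j < w; ++j) acc[j] += xp[j];
    ++used;
  }
  return List::create(_["sum"] = acc, _["n"] = used);
}

// Accumulate cyclic-shift surrogate STA windows for one trial from its
// circular spike-current cross-correlation c (length N). For surrogate s with
// shift d samples, the shifted STA window is c[(lag + d) mod N].
// [[Rcpp::export]]
void cpp_shift_accumulate(NumericVector cc, IntegerVector shifts, int halfw,
                          NumericMatrix acc) {
  int n = cc.size(), w = 2 * halfw + 1;
  for (int s = 0; s < shifts.size(); ++s) {
    int d = shifts[s];
    for (int j = 0; j < w; ++j) {
      int idx = (j - halfw + d) % n;
      if (idx < 0) idx += n;
      acc(j, s) += cc[idx];
    }
  }
}
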