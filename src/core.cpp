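// Fixed-step RK4 core for the closed-loop circulation model.
//
// State vector y (9 doubles):
//   0 V_lv  left-ventricular volume            [mL]
//   1 V_sa  systemic arterial (aortic) volume  [mL]
//   2 V_sv  systemic venous volume             [mL]
//   3 V_ra  right atrial volume                [mL]
//   4 V_rv  right-ventricular volume           [mL]
//   5 V_pa  pulmonary arterial volume          [mL]
//   6 V_pv  pulmonary venous / left atrial vol [mL]
//   7 MAoP  low-pass filtered aortic pressure  [mmHg]
//   8 Sy    sympathetic modulation             [FGU]
//
// The cardiac clock (phase within the beat, current beat period) is a
// discrete state advanced in lockstep with the grid; heart rate takes
// effect at beat onsets only, so systole timing is never cut short.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  // passive compartments: compliance, unstressed volume, intrathoracic flag
  double c_sa, v0_sa;
  double c_sv, v0_sv;          // v0_sv is the venoconstriction-controlled V0
  double c_ra, v0_ra;
  double c_pa, v0_pa;
  double c_pv, v0_pv;
  // ventricles
  double lv_gain, lv_escale, lv_v0, lv_cpass;
  double rv_gain, rv_escale, rv_v0, rv_cpass;
  double sys_dur, act_peak_frac;
  // resistors [U = mmHg s/mL]
  double r_mit, r_av, sten_sev, sten_scale;
  double r_sys, r_ven, r_tri, r_rvout, r_pul;
  // respiration
  double itp_mean, itp_amp, itp_period;
  // controller
  double setpoint, tau_maop, gain_fb, sy_baseline, sy_min, sy_max, tau_sy;
  double hr_base, hr_slope, hr_min, hr_max;
  double ino_slope, limiter, kven, kven_sat, v0sv_min_frac, v0sv_max_frac;
  bool hr_on, lv_ino_on, rv_ino_on, ven_on;
  double clamp_hr, clamp_sy;   // NaN = no clamp
};

static Pars unpack(const List& p) {
  Pars q;
  q.c_sa = p["c_sa"];   q.v0_sa = p["v0_sa"];
  q.c_sv = p["c_sv"];   q.v0_sv = p["v0_sv"];
  q.c_ra = p["c_ra"];   q.v0_ra = p["v0_ra"];
  q.c_pa = p["c_pa"];   q.v0_pa = p["v0_pa"];
  q.c_pv = p["c_pv"];   q.v0_pv = p["v0_pv"];
  q.lv_gain = p["lv_gain"]; q.lv_escale = p["lv_escale"];
  q.lv_v0 = p["lv_v0"];     q.lv_cpass = p["lv_cpass"];
  q.rv_gain = p["rv_gain"]; q.rv_escale = p["rv_escale"];
  q.rv_v0 = p["rv_v0"];     q.rv_cpass = p["rv_cpass"];
  q.sys_dur = p["sys_dur"]; q.act_peak_frac = p["act_peak_frac"];
  q.r_mit = p["r_mit"]; q.r_av = p["r_av"];
  q.sten_sev = p["sten_sev"]; q.sten_scale = p["sten_scale"];
  q.r_sys = p["r_sys"]; q.r_ven = p["r_ven"]; q.r_tri = p["r_tri"];
  q.r_rvout = p["r_rvout"]; q.r_pul = p["r_pul"];
  q.itp_mean = p["itp_mean"]; q.itp_amp = p["itp_amp"];
  q.itp_period = p["itp_period"];
  q.setpoint = p["setpoint"]; q.tau_maop = p["tau_maop"];
  q.gain_fb = p["gain_fb"]; q.sy_baseline = p["sy_baseline"];
  q.sy_min = p["sy_min"]; q.sy_max = p["sy_max"]; q.tau_sy = p["tau_sy"];
  q.hr_base = p["hr_base"]; q.hr_slope = p["hr_slope"];
  q.hr_min = p["hr_min"]; q.hr_max = p["hr_max"];
  q.ino_slope = p["ino_slope"]; q.limiter = p["limiter"];
  q.kven = p["kven"]; q.kven_sat = p["kven_sat"];
  q.v0sv_min_frac = p["v0sv_min_frac"]; q.v0sv_max_frac = p["v0sv_max_frac"];
  q.hr_on = as<bool>(p["hr_on"]);  q.lv_ino_on = as<bool>(p["lv_ino_on"]);
  q.rv_ino_on = as<bool>(p["rv_ino_on"]); q.ven_on = as<bool>(p["ven_on"]);
  q.clamp_hr = p["clamp_hr"]; q.clamp_sy = p["clamp_sy"];
  return q;
}

static inline double clipd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// skewed sinusoidal activation: quarter-sine rise to 1 at peak_frac*Ts,
// quarter-cosine fall back to 0 at Ts; zero outside (0, Ts)
static inline double activation(double phase, double ts, double peak_frac) {
  if (phase <= 0.0 || phase >= ts) return 0.0;
  const double tp = peak_frac * ts;
  if (phase < tp) return std::sin(M_PI_2 * phase / tp);
  return std::cos(M_PI_2 * (phase - tp) / (ts - tp));
}

static inline double itp_at(double t, const Pars& q) {
  return q.itp_mean + q.itp_amp * std::sin(2.0 * M_PI * t / q.itp_period);
}

static inline double fwd(double dp, double r) {   // ideal diode
  return dp > 0.0 ? dp / r : 0.0;
}

struct Pressures {
  double lv, sa, sv, ra, rv, pa, pv;
};

static Pressures pressures(const double* y, double a, double itp,
                           double e_lv, double e_rv, double v0sv_eff,
                           const Pars& q) {
  Pressures pr;
  pr.lv = itp + a * e_lv * (y[0] - q.lv_v0) + (y[0] - q.lv_v0) / q.lv_cpass;
  pr.sa = (y[1] - q.v0_sa) / q.c_sa;
  pr.sv = (y[2] - v0sv_eff) / q.c_sv;
  pr.ra = itp + (y[3] - q.v0_ra) / q.c_ra;
  pr.rv = itp + a * e_rv * (y[4] - q.rv_v0) + (y[4] - q.rv_v0) / q.rv_cpass;
  pr.pa = itp + (y[5] - q.v0_pa) / q.c_pa;
  pr.pv = itp + (y[6] - q.v0_pv) / q.c_pv;
  return pr;
}

// effective elastance from nominal gain through the inotropic limiter
static inline double elastance(double gain, double escale, double drive,
                               const Pars& q) {
  double d = drive < 0.0 ? 0.0 : (drive > q.limiter ? q.limiter : drive);
  return escale * (gain * (1.0 + q.ino_slope * d)) / 100.0;
}

static void derivs(double t, const double* y, double phase_ref, double t_ref,
                   const Pars& q, const double* frozen, double* dy) {
  const double sy = std::isnan(q.clamp_sy) ? y[8] : q.clamp_sy;
  const double itp = itp_at(t, q);
  const double phase = phase_ref + (t - t_ref);
  const double a = activation(phase, q.sys_dur, q.act_peak_frac);

  const double lvd = q.lv_ino_on ? sy : frozen[1];
  const double rvd = q.rv_ino_on ? sy : frozen[2];
  const double vde = q.ven_on
    ? q.kven_sat * std::tanh(q.kven * (sy - q.sy_baseline) / q.kven_sat)
    : frozen[3];
  const double v0sv_eff = clipd(q.v0_sv - vde, q.v0sv_min_frac * q.v0_sv,
                                q.v0sv_max_frac * q.v0_sv);

  const double e_lv = elastance(q.lv_gain, q.lv_escale, lvd, q);
  const double e_rv = elastance(q.rv_gain, q.rv_escale, rvd, q);
  const Pressures pr = pressures(y, a, itp, e_lv, e_rv, v0sv_eff, q);

  const double q_mit = fwd(pr.pv - pr.lv, q.r_mit);
  const double q_av  = fwd(pr.lv - pr.sa, q.r_av + q.sten_sev * q.sten_scale);
  const double q_sys = (pr.sa - pr.sv) / q.r_sys;
  const double q_ven = (pr.sv - pr.ra) / q.r_ven;
  const double q_tri = fwd(pr.ra - pr.rv, q.r_tri);
  const double q_pvl = fwd(pr.rv - pr.pa, q.r_rvout);
  const double q_pul = (pr.pa - pr.pv) / q.r_pul;

  dy[0] = q_mit - q_av;
  dy[1] = q_av  - q_sys;
  dy[2] = q_sys - q_ven;
  dy[3] = q_ven - q_tri;
  dy[4] = q_tri - q_pvl;
  dy[5] = q_pvl - q_pul;
  dy[6] = q_pul - q_mit;
  dy[7] = (pr.sa - y[7]) / q.tau_maop;
  if (std::isnan(q.clamp_sy)) {
    const double syt = clipd(q.sy_baseline + q.gain_fb * (q.setpoint - y[7]),
                             q.sy_min, q.sy_max);
    dy[8] = (syt - y[8]) / q.tau_sy;
  } else {
    dy[8] = 0.0;
  }
}

// single derivative evaluation, exposed for cross-checks against the R-level
// mass-balance implementation
// [[Rcpp::export]]
NumericVector cv_core_derivs(NumericVector y, double t, double phase,
                             List params, NumericVector frozen) {
  Pars q = unpack(params);
  double dy[9];
  derivs(t, REAL(y), phase, t, q, REAL(frozen), dy);
  NumericVector out(9);
  for (int i = 0; i < 9; ++i) out[i] = dy[i];
  out.attr("names") = CharacterVector::create(
    "V_lv", "V_sa", "V_sv", "V_ra", "V_rv", "V_pa", "V_pv", "MAoP", "Sy");
  return out;
}

// [[Rcpp::export]]
List cv_core_integrate(NumericVector y0, double t0, double t1, double dt,
                       List params, double phase0, double period0,
                       NumericVector frozen0, double co0, double edv0,
                       double minv0) {
  Pars q = unpack(params);
  const int n = (int)std::lround((t1 - t0) / dt);
  if (n < 1) stop("time span shorter than one step");

  NumericMatrix tr(n + 1, 11);
  colnames(tr) = CharacterVector::create(
    "t", "AoP", "MAoP", "LVP", "LAtP", "CO", "CVV", "Sy", "HR", "LVV", "ITP");
  NumericMatrix vols(n + 1, 7);
  colnames(vols) = CharacterVector::create(
    "V_lv", "V_sa", "V_sv", "V_ra", "V_rv", "V_pa", "V_pv");

  double y[9];
  for (int i = 0; i < 9; ++i) y[i] = y0[i];
  double frozen[4];
  for (int i = 0; i < 4; ++i) frozen[i] = frozen0[i];
  double phase = phase0, period = period0;
  double co = co0, edv = edv0, minv = minv0;
  std::vector<double> onsets;

  double k1[9], k2[9], k3[9], k4[9], yt[9];

  for (int i = 0; i <= n; ++i) {
    const double t = t0 + i * dt;
    const double sy = std::isnan(q.clamp_sy) ? y[8] : q.clamp_sy;

    // refresh frozen effector memory while the corresponding limb is on
    if (q.hr_on) frozen[0] = clipd(q.hr_base + q.hr_slope * (sy - q.sy_baseline),
                                   q.hr_min, q.hr_max);
    if (q.lv_ino_on) frozen[1] = sy;
    if (q.rv_ino_on) frozen[2] = sy;
    if (q.ven_on)
      frozen[3] = q.kven_sat * std::tanh(q.kven * (sy - q.sy_baseline) /
                                         q.kven_sat);

    // record the current sample
    {
      const double itp = itp_at(t, q);
      const double a = activation(phase, q.sys_dur, q.act_peak_frac);
      const double e_lv = elastance(q.lv_gain, q.lv_escale, frozen[1], q);
      const double e_rv = elastance(q.rv_gain, q.rv_escale, frozen[2], q);
      const double v0sv_eff = clipd(q.v0_sv - frozen[3],
                                    q.v0sv_min_frac * q.v0_sv,
                                    q.v0sv_max_frac * q.v0_sv);
      const Pressures pr = pressures(y, a, itp, e_lv, e_rv, v0sv_eff, q);
      if (!std::isfinite(pr.lv) || !std::isfinite(pr.sa) ||
          std::fabs(pr.lv) > 1e4 || std::fabs(pr.sa) > 1e4)
        stop("integration unstable at t = %f s (|pressure| > 1e4 mmHg)", t);
      tr(i, 0) = t;
      tr(i, 1) = pr.sa;
      tr(i, 2) = y[7];
      tr(i, 3) = pr.lv;
      tr(i, 4) = pr.pv;
      tr(i, 5) = co;
      tr(i, 6) = v0sv_eff;
      tr(i, 7) = sy;
      tr(i, 8) = 60.0 / period;
      tr(i, 9) = y[0];
      tr(i, 10) = itp;
      for (int j = 0; j < 7; ++j) vols(i, j) = y[j];
    }
    if (i == n) break;

    // classic RK4 step
    derivs(t, y, phase, t, q, frozen, k1);
    for (int j = 0; j < 9; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    derivs(t + 0.5 * dt, yt, phase, t, q, frozen, k2);
    for (int j = 0; j < 9; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    derivs(t + 0.5 * dt, yt, phase, t, q, frozen, k3);
    for (int j = 0; j < 9; ++j) yt[j] = y[j] + dt * k3[j];
    derivs(t + dt, yt, phase, t, q, frozen, k4);
    for (int j = 0; j < 9; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    y[8] = clipd(y[8], q.sy_min, q.sy_max);

    if (y[0] < minv) minv = y[0];
    phase += dt;
    if (phase >= period) {
      // beat completed: log onset of the new beat, apply current HR effector
      co = (edv - minv) * 60.0 / period;
      const double t_onset = (t + dt) - (phase - period);
      onsets.push_back(t_onset);
      phase -= period;
      const double sy_now = std::isnan(q.clamp_sy) ? y[8] : q.clamp_sy;
      double hr = std::isnan(q.clamp_hr)
        ? (q.hr_on ? clipd(q.hr_base + q.hr_slope * (sy_now - q.sy_baseline),
                           q.hr_min, q.hr_max)
                   : frozen[0])
        : q.clamp_hr;
      period = 60.0 / hr;
      edv = y[0];
      minv = y[0];
    }
  }

  NumericVector yout(9);
  for (int i = 0; i < 9; ++i) yout[i] = y[i];
  NumericVector fout(4);
  for (int i = 0; i < 4; ++i) fout[i] = frozen[i];

  return List::create(
    _["trace"] = tr,
    _["volumes"] = vols,
    _["onsets"] = wrap(onsets),
    _["state"] = List::create(
      _["y"] = yout, _["phase"] = phase, _["period"] = period,
      _["frozen"] = fout, _["co"] = co, _["edv"] = edv, _["minv"] = minv));
}
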