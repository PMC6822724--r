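#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

// Oscillator parameters with the feedback delay snapped to the step grid.
struct OscPar {
  double alpha, beta1, beta2, eps, f, D, A, delta;
  int tau_steps;
};

static OscPar as_oscpar(const List& par, double dt) {
  OscPar p;
  p.alpha = as<double>(par["alpha"]);
  p.beta1 = as<double>(par["beta1"]);
  p.beta2 = as<double>(par["beta2"]);
  p.eps   = as<double>(par["epsilon"]);
  p.f     = as<double>(par["f"]);
  p.D     = as<double>(par["D"]);
  p.A     = as<double>(par["A"]);
  p.delta = as<double>(par["delta"]);
  double tau = as<double>(par["tau"]);
  p.tau_steps = (int) std::llround(tau / dt);
  return p;
}

// dz/dt = (f + delta) * [ z (alpha + i2pi + beta1|z|^2 + eps beta2 |z|^4 / (1 - eps|z|^2)) + F ]
//         - D * z(t - tau)
static inline cplx rhs(const OscPar& p, const cplx& z, const cplx& zd, const cplx& F,
                       double t) {
  double r2 = std::norm(z);
  cplx nl(p.alpha + p.beta1 * r2, 2.0 * M_PI);
  if (p.eps != 0.0) {
    double den = 1.0 - p.eps * r2;
    if (den <= 0.0)
      stop("singular denominator: epsilon*|z|^2 >= 1 at t = %f", t);
    nl += p.eps * p.beta2 * r2 * r2 / den;
  }
  return (p.f + p.delta) * (z * nl + F) - p.D * zd;
}

// Linear interpolation into the history buffer; constant pre-history for t <= 0.
// imax is the last filled index (current step start).
static inline cplx lookup(const std::vector<cplx>& buf, double dt, double tq, int imax) {
  if (tq <= 0.0) return buf[0];
  double x = tq / dt;
  int i = (int) std::floor(x);
  if (i >= imax) return buf[imax];
  double w = x - i;
  return (1.0 - w) * buf[i] + w * buf[i + 1];
}

// Delayed self-feedback at a stage time; tau = 0 means instantaneous (use stage state).
static inline cplx self_delayed(const OscPar& p, const std::vector<cplx>& buf,
                                double dt, double t_stage, int imax, const cplx& z_stage) {
  if (p.D == 0.0) return cplx(0.0, 0.0);
  if (p.tau_steps == 0) return z_stage;
  return lookup(buf, dt, t_stage - p.tau_steps * dt, imax);
}

static inline void check_finite(const cplx& z, double t) {
  if (!std::isfinite(z.real()) || !std::isfinite(z.imag()))
    stop("integration blew up (non-finite state) at t = %f", t);
}

// Stimulus kinds: 0 none, 1 sinusoid, 2 antiphase_sinusoid, 3 square_wave, 4 self_only
// Feedback modes (single): 0 off, 1 constant_self, 2 half_cycle_self
static inline cplx stim_single(double t, double fs, int kind, int feedback,
                               bool normalize, double A, const cplx& z) {
  if (kind == 4) return A * z;
  if (kind == 0) return cplx(0.0, 0.0);
  double ph = 2.0 * M_PI * fs * t;
  cplx c;
  if (kind == 3) {
    c = cplx(std::cos(ph) >= 0.0 ? 1.0 : -1.0, 0.0);
  } else {
    c = cplx(std::cos(ph), std::sin(ph));
    if (kind == 2) c = -c;
  }
  bool combine = (feedback == 1);
  if (feedback == 2) {
    double x = fs * t;
    double frac = x - std::floor(x);
    combine = (frac >= 0.5);  // stimulus phase in [pi, 2pi)
  }
  if (!combine) return c;
  cplx u = c + A * z;
  if (normalize) {
    // at the (measure-zero) degenerate point the normalized direction is
    // undefined; use zero input for that stage and continue
    double m = std::abs(u);
    u = (m < 1e-12) ? cplx(0.0, 0.0) : u / m;
  }
  return u;
}

static ComplexVector to_rcomplex(const std::vector<cplx>& v) {
  ComplexVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    out[i].r = v[i].real();
    out[i].i = v[i].imag();
  }
  return out;
}

// [[Rcpp::export]]
List integrate_single_cpp(List par, int kind, int feedback, bool normalize,
                          double fs, double duration, double dt,
                          double init_re, double init_im) {
  OscPar p = as_oscpar(par, dt);
  int n = (int) std::llround(duration / dt);
  std::vector<cplx> z(n + 1), F(n + 1);
  z[0] = cplx(init_re, init_im);
  double h = dt;
  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    cplx zi = z[i];
    cplx F1 = stim_single(t, fs, kind, feedback, normalize, p.A, zi);
    cplx k1 = rhs(p, zi, self_delayed(p, z, dt, t, i, zi), F1, t);
    cplx z2 = zi + 0.5 * h * k1;
    cplx k2 = rhs(p, z2, self_delayed(p, z, dt, t + 0.5 * h, i, z2),
                  stim_single(t + 0.5 * h, fs, kind, feedback, normalize, p.A, z2),
                  t + 0.5 * h);
    cplx z3 = zi + 0.5 * h * k2;
    cplx k3 = rhs(p, z3, self_delayed(p, z, dt, t + 0.5 * h, i, z3),
                  stim_single(t + 0.5 * h, fs, kind, feedback, normalize, p.A, z3),
                  t + 0.5 * h);
    cplx z4 = zi + h * k3;
    cplx k4 = rhs(p, z4, self_delayed(p, z, dt, t + h, i, z4),
                  stim_single(t + h, fs, kind, feedback, normalize, p.A, z4),
                  t + h);
    cplx zn = zi + (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    check_finite(zn, t + h);
    z[i + 1] = zn;
    F[i] = F1;
  }
  F[n] = stim_single(n * dt, fs, kind, feedback, normalize, p.A, z[n]);
  NumericVector times(n + 1);
  for (int i = 0; i <= n; ++i) times[i] = i * dt;
  return List::create(_["time"] = times, _["z"] = to_rcomplex(z),
                      _["F"] = to_rcomplex(F));
}

// Duet: two oscillators share one external sinusoid (signs +/-) on one grid.
// With feedback on, each model adds A*z(k), k toggling self -> partner each
// half stimulus cycle (k = self on the first half).
static inline cplx stim_duet(double t, double fs, bool feedback, bool normalize,
                             double A, const cplx& z_self, const cplx& z_partner,
                             int sign) {
  double ph = 2.0 * M_PI * fs * t;
  cplx c = cplx(std::cos(ph), std::sin(ph));
  if (sign < 0) c = -c;
  if (!feedback) return c;
  double x = fs * t;
  double frac = x - std::floor(x);
  cplx zk = (frac < 0.5) ? z_self : z_partner;
  cplx u = c + A * zk;
  if (normalize) {
    double m = std::abs(u);
    u = (m < 1e-12) ? cplx(0.0, 0.0) : u / m;
  }
  return u;
}

// [[Rcpp::export]]
List integrate_duet_cpp(List par1, List par2, double fs, bool feedback,
                        bool normalize, double duration, double dt,
                        double init_re, double init_im) {
  OscPar p1 = as_oscpar(par1, dt), p2 = as_oscpar(par2, dt);
  int n = (int) std::llround(duration / dt);
  std::vector<cplx> z1(n + 1), z2(n + 1), F1(n + 1), F2(n + 1);
  z1[0] = z2[0] = cplx(init_re, init_im);
  double h = dt;
  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    cplx a = z1[i], b = z2[i];
    cplx k1a, k1b, k2a, k2b, k3a, k3b, k4a, k4b;
    // joint RK4: both oscillators advance on shared stage values
    {
      cplx Fa = stim_duet(t, fs, feedback, normalize, p1.A, a, b, +1);
      cplx Fb = stim_duet(t, fs, feedback, normalize, p2.A, b, a, -1);
      k1a = rhs(p1, a, self_delayed(p1, z1, dt, t, i, a), Fa, t);
      k1b = rhs(p2, b, self_delayed(p2, z2, dt, t, i, b), Fb, t);
      F1[i] = Fa;
      F2[i] = Fb;
    }
    {
      double ts = t + 0.5 * h;
      cplx as = a + 0.5 * h * k1a, bs = b + 0.5 * h * k1b;
      cplx Fa = stim_duet(ts, fs, feedback, normalize, p1.A, as, bs, +1);
      cplx Fb = stim_duet(ts, fs, feedback, normalize, p2.A, bs, as, -1);
      k2a = rhs(p1, as, self_delayed(p1, z1, dt, ts, i, as), Fa, ts);
      k2b = rhs(p2, bs, self_delayed(p2, z2, dt, ts, i, bs), Fb, ts);
    }
    {
      double ts = t + 0.5 * h;
      cplx as = a + 0.5 * h * k2a, bs = b + 0.5 * h * k2b;
      cplx Fa = stim_duet(ts, fs, feedback, normalize, p1.A, as, bs, +1);
      cplx Fb = stim_duet(ts, fs, feedback, normalize, p2.A, bs, as, -1);
      k3a = rhs(p1, as, self_delayed(p1, z1, dt, ts, i, as), Fa, ts);
      k3b = rhs(p2, bs, self_delayed(p2, z2, dt, ts, i, bs), Fb, ts);
    }
    {
      double ts = t + h;
      cplx as = a + h * k3a, bs = b + h * k3b;
      cplx Fa = stim_duet(ts, fs, feedback, normalize, p1.A, as, bs, +1);
      cplx Fb = stim_duet(ts, fs, feedback, normalize, p2.A, bs, as, -1);
      k4a = rhs(p1, as, self_delayed(p1, z1, dt, ts, i, as), Fa, ts);
      k4b = rhs(p2, bs, self_delayed(p2, z2, dt, ts, i, bs), Fb, ts);
    }
    cplx na = a + (h / 6.0) * (k1a + 2.0 * k2a + 2.0 * k3a + k4a);
    cplx nb = b + (h / 6.0) * (k1b + 2.0 * k2b + 2.0 * k3b + k4b);
    check_finite(na, t + h);
    check_finite(nb, t + h);
    z1[i + 1] = na;
    z2[i + 1] = nb;
  }
  F1[n] = stim_duet(n * dt, fs, feedback, normalize, p1.A, z1[n], z2[n], +1);
  F2[n] = stim_duet(n * dt, fs, feedback, normalize, p2.A, z2[n], z1[n], -1);
  NumericVector times(n + 1);
  for (int i = 0; i <= n; ++i) times[i] = i * dt;
  return List::create(_["time"] = times,
                      _["z1"] = to_rcomplex(z1), _["F1"] = to_rcomplex(F1),
                      _["z2"] = to_rcomplex(z2), _["F2"] = to_rcomplex(F2));
}

// Turn-taking: no external sinusoid. The active oscillator receives its own
// state scaled by its self coefficient; the passive one receives the active
// oscillator's state delayed by the transmission latency, coefficient +1.
// Turns switch when the active oscillator's unwrapped phase has advanced by
// 2*pi since its turn began. Oscillator 1 initiates.
// [[Rcpp::export]]
List integrate_turns_cpp(List par1, List par2, double tl, double duration,
                         double dt, double init_re, double init_im,
                         bool literal_joiner_sign) {
  OscPar p[2] = { as_oscpar(par1, dt), as_oscpar(par2, dt) };
  double selfcoef[2] = { p[0].A, literal_joiner_sign ? -p[1].A : p[1].A };
  int tl_steps = (int) std::llround(tl / dt);
  int n = (int) std::llround(duration / dt);
  std::vector<cplx> z[2], F[2];
  z[0].resize(n + 1); z[1].resize(n + 1);
  F[0].resize(n + 1); F[1].resize(n + 1);
  z[0][0] = z[1][0] = cplx(init_re, init_im);
  int active = 0;
  double phase_acc = 0.0, turn_start = 0.0;
  std::vector<double> turn_starts;
  std::vector<int> turn_active;
  turn_starts.push_back(0.0);
  turn_active.push_back(1);
  double h = dt;
  // give up if the active turn lasts much longer than its natural period
  double lockup_span = 10.0 / std::min(p[0].f + p[0].delta, p[1].f + p[1].delta);
  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    if (t - turn_start > lockup_span)
      stop("turn alternation locked up: no phase completion since t = %f", turn_start);
    int act = active, pas = 1 - active;
    cplx s[2] = { z[0][i], z[1][i] };
    cplx k[4][2];
    double stage_t[4] = { t, t + 0.5 * h, t + 0.5 * h, t + h };
    double stage_w[4] = { 0.0, 0.5, 0.5, 1.0 };
    cplx cur[2] = { s[0], s[1] };
    cplx Fa0, Fp0;
    for (int st = 0; st < 4; ++st) {
      double ts = stage_t[st];
      if (st > 0) {
        cur[0] = s[0] + stage_w[st] * h * k[st - 1][0];
        cur[1] = s[1] + stage_w[st] * h * k[st - 1][1];
      }
      cplx Fa = selfcoef[act] * cur[act];
      cplx Fp = (tl_steps == 0) ? cur[act]
                                : lookup(z[act], dt, ts - tl_steps * dt, i);
      if (st == 0) { Fa0 = Fa; Fp0 = Fp; }
      cplx Fin[2];
      Fin[act] = Fa;
      Fin[pas] = Fp;
      for (int m = 0; m < 2; ++m)
        k[st][m] = rhs(p[m], cur[m], self_delayed(p[m], z[m], dt, ts, i, cur[m]),
                       Fin[m], ts);
    }
    for (int m = 0; m < 2; ++m) {
      cplx nz = s[m] + (h / 6.0) * (k[0][m] + 2.0 * k[1][m] + 2.0 * k[2][m] + k[3][m]);
      check_finite(nz, t + h);
      z[m][i + 1] = nz;
    }
    F[act][i] = Fa0;
    F[pas][i] = Fp0;
    phase_acc += std::arg(z[act][i + 1] * std::conj(z[act][i]));
    // turn ends at the active oscillator's cycle completion: its phase
    // crossing 0 upward (a Re(z) crest), at least half a cycle into the turn
    double a_prev = std::arg(z[act][i]);
    double a_new = std::arg(z[act][i + 1]);
    if (phase_acc >= M_PI && a_prev < 0.0 && a_new >= 0.0 &&
        (a_new - a_prev) < M_PI) {
      active = 1 - active;
      phase_acc = 0.0;
      turn_start = t + h;
      turn_starts.push_back(turn_start);
      turn_active.push_back(active + 1);
    }
  }
  F[active][n] = selfcoef[active] * z[active][n];
  F[1 - active][n] = (tl_steps == 0)
                         ? z[active][n]
                         : lookup(z[active], dt, n * dt - tl_steps * dt, n);
  NumericVector times(n + 1);
  for (int i = 0; i <= n; ++i) times[i] = i * dt;
  return List::create(_["time"] = times,
                      _["z1"] = to_rcomplex(z[0]), _["F1"] = to_rcomplex(F[0]),
                      _["z2"] = to_rcomplex(z[1]), _["F2"] = to_rcomplex(F[1]),
                      _["turn_start"] = wrap(turn_starts),
                      _["turn_active"] = wrap(turn_active));
}
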