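// Conductance-based single-compartment neuron with IKLT: vector field,
// resting-state relaxation, and adaptive 5th-order (Cash-Karp) integration
// with dense voltage output on a uniform grid.
//
// Units: V mV, t ms, C pF, g nS, I pA (nS * mV = pA; pA / pF = mV/ms).
// State vector (11): V, m, h, n, p, w, z, a, b, c, r
// Parameter vector (11): C, g_lk, E_lk, g_Na, E_Na, g_KA, g_KHT, g_KLT,
//                        E_K, g_h, E_h

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int NSTATE = 11;

struct Params {
  double C, g_lk, E_lk, g_Na, E_Na, g_KA, g_KHT, g_KLT, E_K, g_h, E_h;
  double phi;  // gating-rate scale (temperature correction); 1 = reference
};

static Params unpack(const NumericVector& p) {
  if (p.size() != 11 && p.size() != 12)
    stop("parameter vector must have 11 or 12 elements");
  Params q;
  q.C = p[0]; q.g_lk = p[1]; q.E_lk = p[2]; q.g_Na = p[3]; q.E_Na = p[4];
  q.g_KA = p[5]; q.g_KHT = p[6]; q.g_KLT = p[7]; q.E_K = p[8];
  q.g_h = p[9]; q.E_h = p[10];
  q.phi = (p.size() == 12) ? p[11] : 1.0;
  if (q.C <= 0) stop("capacitance must be positive");
  if (q.phi <= 0) stop("rate scale must be positive");
  return q;
}

// Steady-state activations and time constants (ms) of the ventral cochlear
// nucleus channel family of Rothman & Manis (2003), with three adjustments
// that adapt the kinetics to cortical-level (CM) membrane scales so that
// the zero-gKLT cell fires tonically and the high-gKLT cell phasically:
//   * Na inactivation (h) midpoint depolarized by 10 mV (slow subthreshold
//     depolarizations no longer inactivate Na before threshold is reached);
//   * high-threshold K (n, p) midpoints hyperpolarized by 15 mV (spikes
//     repolarize against strong drive through the high-resistance leak);
//   * all time constants halved (rate correction toward avian body
//     temperature from the reference temperature of the source model).
// HSH/KSH are those midpoint shifts; TSC the time-constant scale.
static const double HSH = 10.0;
static const double KSH = 15.0;
static const double WSH = 0.0;   // KLT activation midpoint shift (depolarizing)
static const double TSC = 0.5;
static inline double minf(double V){ return 1.0/(1.0+std::exp(-(V+38.0)/7.0)); }
static inline double taum(double V){ return TSC*(10.0/(5.0*std::exp((V+60.0)/18.0)+36.0*std::exp(-(V+60.0)/25.0))+0.04); }
static inline double hinf(double V){ return 1.0/(1.0+std::exp((V-HSH+65.0)/6.0)); }
static inline double tauh(double V){ return TSC*(100.0/(7.0*std::exp((V-HSH+60.0)/11.0)+10.0*std::exp(-(V-HSH+60.0)/25.0))+0.6); }
static inline double ninf(double V){ return std::pow(1.0+std::exp(-(V+KSH+15.0)/5.0), -0.5); }
static inline double taun(double V){ return TSC*(100.0/(11.0*std::exp((V+KSH+60.0)/24.0)+21.0*std::exp(-(V+KSH+60.0)/23.0))+0.7); }
static inline double pinf(double V){ return 1.0/(1.0+std::exp(-(V+KSH+23.0)/6.0)); }
static inline double taup(double V){ return TSC*(100.0/(4.0*std::exp((V+KSH+60.0)/32.0)+5.0*std::exp(-(V+KSH+60.0)/22.0))+5.0); }
static inline double winf(double V){ return std::pow(1.0+std::exp(-(V-WSH+48.0)/6.0), -0.25); }
static inline double tauw(double V){ return TSC*(100.0/(6.0*std::exp((V-WSH+60.0)/6.0)+16.0*std::exp(-(V-WSH+60.0)/45.0))+1.5); }
static inline double zinf(double V){ return 0.5+0.5/(1.0+std::exp((V+71.0)/10.0)); }
static inline double tauz(double V){ return TSC*(1000.0/(std::exp((V+60.0)/20.0)+std::exp(-(V+60.0)/8.0))+50.0); }
static inline double ainf(double V){ return std::pow(1.0+std::exp(-(V+31.0)/6.0), -0.25); }
static inline double taua(double V){ return TSC*(100.0/(7.0*std::exp((V+60.0)/14.0)+29.0*std::exp(-(V+60.0)/24.0))+0.1); }
static inline double binf(double V){ return std::pow(1.0+std::exp((V+66.0)/7.0), -0.5); }
static inline double taub(double V){ return TSC*(1000.0/(14.0*std::exp((V+60.0)/27.0)+29.0*std::exp(-(V+60.0)/24.0))+1.0); }
static inline double cinf(double V){ return std::pow(1.0+std::exp((V+66.0)/7.0), -0.5); }
static inline double tauc(double V){ return TSC*(90.0/(1.0+std::exp(-(V+66.0)/17.0))+10.0); }
static inline double rinf(double V){ return 1.0/(1.0+std::exp((V+76.0)/7.0)); }
static inline double taur(double V){ return TSC*(1.0e5/(237.0*std::exp((V+60.0)/12.0)+17.0*std::exp(-(V+60.0)/14.0))+25.0); }

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

static inline void deriv(const double* y, double i_total, const Params& q,
                         double* dy) {
  const double V = y[0];
  const double m = clamp01(y[1]), h = clamp01(y[2]);
  const double n = clamp01(y[3]), p = clamp01(y[4]);
  const double w = clamp01(y[5]), z = clamp01(y[6]);
  const double a = clamp01(y[7]), b = clamp01(y[8]), c = clamp01(y[9]);
  const double r = clamp01(y[10]);

  const double i_Na  = q.g_Na * m*m*m*h * (V - q.E_Na);
  const double i_KHT = q.g_KHT * (0.85*n*n + 0.15*p) * (V - q.E_K);
  const double i_KLT = q.g_KLT * w*w*w*w*z * (V - q.E_K);
  const double i_KA  = q.g_KA * a*a*a*a*b*c * (V - q.E_K);
  const double i_h   = q.g_h * r * (V - q.E_h);
  const double i_lk  = q.g_lk * (V - q.E_lk);

  const double phi = q.phi;
  dy[0] = (-i_Na - i_KHT - i_KLT - i_KA - i_h - i_lk + i_total) / q.C;
  dy[1] = phi * (minf(V) - m) / taum(V);
  dy[2] = phi * (hinf(V) - h) / tauh(V);
  dy[3] = phi * (ninf(V) - n) / taun(V);
  dy[4] = phi * (pinf(V) - p) / taup(V);
  dy[5] = phi * (winf(V) - w) / tauw(V);
  dy[6] = phi * (zinf(V) - z) / tauz(V);
  dy[7] = phi * (ainf(V) - a) / taua(V);
  dy[8] = phi * (binf(V) - b) / taub(V);
  dy[9] = phi * (cinf(V) - c) / tauc(V);
  dy[10] = phi * (rinf(V) - r) / taur(V);
}

// Piecewise-linear interpolation of the injected current, sampled every
// dt_in ms; held at the last sample beyond the end of the trace.
struct CurrentInterp {
  const double* samples;
  int n;
  double dt_in;
  double at(double t_ms) const {
    if (n == 0) return 0.0;
    double x = t_ms / dt_in;
    if (x <= 0.0) return samples[0];
    int i = (int)std::floor(x);
    if (i >= n - 1) return samples[n - 1];
    double f = x - i;
    return samples[i] * (1.0 - f) + samples[i + 1] * f;
  }
};

// Cash-Karp embedded Runge-Kutta 5(4) tableau
static const double ck_a[6] = {0.0, 0.2, 0.3, 0.6, 1.0, 0.875};
static const double ck_b[6][5] = {
  {0, 0, 0, 0, 0},
  {0.2, 0, 0, 0, 0},
  {3.0/40.0, 9.0/40.0, 0, 0, 0},
  {0.3, -0.9, 1.2, 0, 0},
  {-11.0/54.0, 2.5, -70.0/27.0, 35.0/27.0, 0},
  {1631.0/55296.0, 175.0/512.0, 575.0/13824.0, 44275.0/110592.0, 253.0/4096.0}
};
static const double ck_c5[6] = {37.0/378.0, 0.0, 250.0/621.0, 125.0/594.0,
                                0.0, 512.0/1771.0};
static const double ck_c4[6] = {2825.0/27648.0, 0.0, 18575.0/48384.0,
                                13525.0/55296.0, 277.0/14336.0, 0.25};

struct StepResult {
  bool accepted;
  double err;
};

// One Cash-Karp attempt from (t, y) with step h; on acceptance writes ynew
// and the derivative at the new point is NOT computed here (FSAL not used).
static StepResult ck_step(double t, const double* y, double h,
                          const CurrentInterp& cur, const Params& q,
                          double tol, double* ynew) {
  double k[6][NSTATE];
  double ytmp[NSTATE];

  deriv(y, cur.at(t), q, k[0]);
  for (int s = 1; s < 6; ++s) {
    for (int i = 0; i < NSTATE; ++i) {
      double acc = 0.0;
      for (int j = 0; j < s; ++j) acc += ck_b[s][j] * k[j][i];
      ytmp[i] = y[i] + h * acc;
    }
    deriv(ytmp, cur.at(t + ck_a[s] * h), q, k[s]);
  }

  double errmax = 0.0;
  for (int i = 0; i < NSTATE; ++i) {
    double y5 = 0.0, y4 = 0.0;
    for (int s = 0; s < 6; ++s) {
      y5 += ck_c5[s] * k[s][i];
      y4 += ck_c4[s] * k[s][i];
    }
    ynew[i] = y[i] + h * y5;
    double err = std::fabs(h * (y5 - y4));
    double scale = tol * (1.0 + std::fabs(y[i]));
    if (err / scale > errmax) errmax = err / scale;
  }
  StepResult res;
  res.err = errmax;
  res.accepted = (errmax <= 1.0) && R_finite(ynew[0]);
  return res;
}

// Adaptive integration over [0, t_end]; if grid_dt > 0, the voltage is
// written on the uniform output grid by cubic Hermite interpolation within
// each accepted step. Returns the final state; fills vout when requested.
static std::vector<double> integrate(std::vector<double> y,
                                     const CurrentInterp& cur,
                                     const Params& q, double t_end,
                                     double tol, double grid_dt,
                                     std::vector<double>* vout,
                                     long* n_steps, long* n_rejected) {
  const double h_max = 1.0;     // never step over input-sample features
  const double h_min = 1e-8;
  double t = 0.0, h = 0.01;
  long nst = 0, nrej = 0;
  double ynew[NSTATE], dy0[NSTATE], dy1[NSTATE];

  int n_out = 0;
  if (grid_dt > 0 && vout) {
    n_out = (int)std::floor(t_end / grid_dt) + 1;
    vout->assign(n_out, NA_REAL);
    (*vout)[0] = y[0];
  }
  int next_out = 1;

  deriv(y.data(), cur.at(0.0), q, dy0);

  while (t < t_end) {
    if (h > t_end - t) h = t_end - t;
    StepResult sr = ck_step(t, y.data(), h, cur, q, tol, ynew);
    if (!sr.accepted) {
      ++nrej;
      double fac = 0.9 * std::pow(sr.err > 0 ? sr.err : 1.0, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < h_min)
        stop("integrator step underflow at t = %g ms", t);
      continue;
    }
    double t_new = t + h;
    if (n_out > 0) {
      deriv(ynew, cur.at(t_new), q, dy1);
      while (next_out < n_out && next_out * grid_dt <= t_new + 1e-12) {
        double tq = next_out * grid_dt;
        double s = (tq - t) / h;          // in (0, 1]
        double s2 = s * s, s3 = s2 * s;
        double h00 = 2*s3 - 3*s2 + 1, h10 = s3 - 2*s2 + s;
        double h01 = -2*s3 + 3*s2,    h11 = s3 - s2;
        (*vout)[next_out] = h00*y[0] + h10*h*dy0[0] +
                            h01*ynew[0] + h11*h*dy1[0];
        ++next_out;
      }
      for (int i = 0; i < NSTATE; ++i) dy0[i] = dy1[i];
    }
    for (int i = 0; i < NSTATE; ++i) y[i] = ynew[i];
    for (int i = 1; i < NSTATE; ++i) y[i] = clamp01(y[i]);
    t = t_new;
    ++nst;
    double fac = 0.9 * std::pow(sr.err > 1e-10 ? sr.err : 1e-10, -0.2);
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h > h_max) h = h_max;
    if (nst % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_steps) *n_steps = nst;
  if (n_rejected) *n_rejected = nrej;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_derivatives(NumericVector state, NumericVector params,
                              double i_total) {
  if (state.size() != NSTATE) stop("state must have 11 elements");
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(state[i])) stop("non-finite state");
  Params q = unpack(params);
  NumericVector out(NSTATE);
  deriv(REAL(state), i_total, q, REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gating_inf(double V) {
  return NumericVector::create(
    _["m"] = minf(V), _["h"] = hinf(V), _["n"] = ninf(V), _["p"] = pinf(V),
    _["w"] = winf(V), _["z"] = zinf(V), _["a"] = ainf(V), _["b"] = binf(V),
    _["c"] = cinf(V), _["r"] = rinf(V));
}

// [[Rcpp::export]]
NumericVector cpp_rest_state(NumericVector params, double t_settle,
                             double tol) {
  Params q = unpack(params);
  std::vector<double> y(NSTATE);
  y[0] = -70.0;
  NumericVector g = cpp_gating_inf(-70.0);
  for (int i = 0; i < 10; ++i) y[i + 1] = g[i];
  CurrentInterp cur; cur.samples = nullptr; cur.n = 0; cur.dt_in = 1.0;
  y = integrate(y, cur, q, t_settle, tol, -1.0, nullptr, nullptr, nullptr);
  return NumericVector(y.begin(), y.end());
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector params, NumericVector i_inj, double dt_in,
                  double dt_out, double tol, NumericVector init) {
  Params q = unpack(params);
  if (init.size() != NSTATE) stop("init must have 11 elements");
  std::vector<double> y(init.begin(), init.end());
  CurrentInterp cur;
  cur.samples = REAL(i_inj);
  cur.n = i_inj.size();
  cur.dt_in = dt_in;
  double t_end = (cur.n > 0 ? cur.n : 1) * dt_in;
  std::vector<double> vout;
  long nst = 0, nrej = 0;
  y = integrate(y, cur, q, t_end, tol, dt_out, &vout, &nst, &nrej);
  return List::create(
    _["voltage"] = NumericVector(vout.begin(), vout.end()),
    _["dt"] = dt_out,
    _["final_state"] = NumericVector(y.begin(), y.end()),
    _["n_steps"] = (double)nst,
    _["n_rejected"] = (double)nrej);
}

// Fixed-step classical RK4 over the same vector field; used for
// convergence checks against the adaptive path.
// [[Rcpp::export]]
NumericVector cpp_simulate_rk4(NumericVector params, NumericVector i_inj,
                               double dt_in, double dt_step, double dt_out,
                               NumericVector init) {
  Params q = unpack(params);
  if (init.size() != NSTATE) stop("init must have 11 elements");
  std::vector<double> y(init.begin(), init.end());
  CurrentInterp cur;
  cur.samples = REAL(i_inj);
  cur.n = i_inj.size();
  cur.dt_in = dt_in;
  double t_end = cur.n * dt_in;
  long n_steps = (long)std::llround(t_end / dt_step);
  int every = (int)std::llround(dt_out / dt_step);
  if (every < 1) stop("dt_out must be >= dt_step");
  int n_out = (int)(n_steps / every) + 1;
  NumericVector vout(n_out, NA_REAL);
  vout[0] = y[0];
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], yt[NSTATE];
  int iout = 1;
  for (long s = 0; s < n_steps; ++s) {
    double t = s * dt_step;
    deriv(y.data(), cur.at(t), q, k1);
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + 0.5 * dt_step * k1[i];
    deriv(yt, cur.at(t + 0.5 * dt_step), q, k2);
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + 0.5 * dt_step * k2[i];
    deriv(yt, cur.at(t + 0.5 * dt_step), q, k3);
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + dt_step * k3[i];
    deriv(yt, cur.at(t + dt_step), q, k4);
    for (int i = 0; i < NSTATE; ++i)
      y[i] += dt_step / 6.0 * (k1[i] + 2*k2[i] + 2*k3[i] + k4[i]);
    for (int i = 1; i < NSTATE; ++i) y[i] = clamp01(y[i]);
    if ((s + 1) % every == 0 && iout < n_out) vout[iout++] = y[0];
    if (s % 1000000 == 0) Rcpp::checkUserInterrupt();
  }
  return vout;
}
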