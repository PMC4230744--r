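#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fast path for the full nigro-cortical model: drift evaluation and the
// time-stepping loops. The R-level implementations in R/model-core.R and
// R/solver.R are the reference surface; these routines must agree with them
// to floating-point round-off (asserted in the test suite).

namespace {

struct Pars {
  double T_Ca, d_Ca, g_Ca, V_Ca;
  double T_K, d_K, g_K, V_K;
  double T_Na, d_Na, g_Na, V_Na;
  double V_L, g_L;
  double V_T, Z_T, d_V, d_Z, Q_Vmax, Q_Zmax;
  double a_ee, a_ei, a_ni, b, phi, tau_K, r_NMDA, delta;
  double V_max, K_m, beta_min, beta_max, m_da, G_min, G_max;
};

double getp(const NumericVector& p, const char* nm) {
  CharacterVector nms = p.names();
  for (int i = 0; i < p.size(); ++i)
    if (std::strcmp(CHAR(STRING_ELT(nms, i)), nm) == 0) return p[i];
  stop("parameter '%s' missing", nm);
  return NA_REAL;  // unreached
}

Pars readPars(const NumericVector& p) {
  Pars q;
  q.T_Ca = getp(p, "T_Ca"); q.d_Ca = getp(p, "d_Ca");
  q.g_Ca = getp(p, "g_Ca"); q.V_Ca = getp(p, "V_Ca");
  q.T_K = getp(p, "T_K"); q.d_K = getp(p, "d_K");
  q.g_K = getp(p, "g_K"); q.V_K = getp(p, "V_K");
  q.T_Na = getp(p, "T_Na"); q.d_Na = getp(p, "d_Na");
  q.g_Na = getp(p, "g_Na"); q.V_Na = getp(p, "V_Na");
  q.V_L = getp(p, "V_L"); q.g_L = getp(p, "g_L");
  q.V_T = getp(p, "V_T"); q.Z_T = getp(p, "Z_T");
  q.d_V = getp(p, "d_V"); q.d_Z = getp(p, "d_Z");
  q.Q_Vmax = getp(p, "Q_Vmax"); q.Q_Zmax = getp(p, "Q_Zmax");
  q.a_ee = getp(p, "a_ee"); q.a_ei = getp(p, "a_ei");
  q.a_ni = getp(p, "a_ni"); q.b = getp(p, "b");
  q.phi = getp(p, "phi"); q.tau_K = getp(p, "tau_K");
  q.r_NMDA = getp(p, "r_NMDA"); q.delta = getp(p, "delta");
  q.V_max = getp(p, "V_max"); q.K_m = getp(p, "K_m");
  q.beta_min = getp(p, "beta_min"); q.beta_max = getp(p, "beta_max");
  q.m_da = getp(p, "m_da");
  q.G_min = getp(p, "G_min"); q.G_max = getp(p, "G_max");
  return q;
}

inline double sigm(double x, double T, double d) {
  return 0.5 * (1.0 + std::tanh((x - T) / d));
}

inline double betaAt(double t_ms, bool task, double cycle_ms, double speech_ms,
                     const Pars& p) {
  if (!task) return p.beta_min;
  double tc = t_ms - std::floor(t_ms / cycle_ms) * cycle_ms;
  return (tc < speech_ms) ? p.beta_max : p.beta_min;
}

inline double gainOf(double c, const Pars& p) {
  return p.G_min + (p.G_max - p.G_min) * std::tanh(p.m_da * c);
}

// State layout: [V(1..N), Z(1..N), W(1..N), c_left, c_right], all 0-based here.
void evalDrift(double t, const std::vector<double>& y, std::vector<double>& out,
               const Pars& p, const NumericMatrix& C, const NumericVector& aie,
               int lmcL, int lmcR, int sncL, int sncR,
               bool task, double cycle_ms, double speech_ms,
               std::vector<double>& QV) {
  const int N = C.nrow();
  const double* V = y.data();
  const double* Z = y.data() + N;
  const double* W = y.data() + 2 * N;
  const double cl = y[3 * N], cr = y[3 * N + 1];
  for (int i = 0; i < N; ++i) QV[i] = p.Q_Vmax * sigm(V[i], p.V_T, p.d_V);
  for (int i = 0; i < N; ++i) {
    double u = 0.0;
    for (int j = 0; j < N; ++j) u += C(i, j) * QV[j];
    double g = 1.0;
    if (i == lmcL) g = gainOf(cl, p);
    else if (i == lmcR) g = gainOf(cr, p);
    const double aee = g * p.a_ee;
    const double mCa = sigm(V[i], p.T_Ca, p.d_Ca);
    const double mNa = sigm(V[i], p.T_Na, p.d_Na);
    const double mK = sigm(V[i], p.T_K, p.d_K);
    const double QZ = p.Q_Zmax * sigm(Z[i], p.Z_T, p.d_Z);
    out[i] = -(p.g_Ca + p.r_NMDA * aee * u) * mCa * (V[i] - p.V_Ca)
             - (p.g_Na * mNa + aee * u) * (V[i] - p.V_Na)
             - p.g_K * W[i] * (V[i] - p.V_K)
             - p.g_L * (V[i] - p.V_L)
             - aie[i] * Z[i] * QZ;
    out[N + i] = p.b * p.a_ei * V[i] * QV[i];
    out[2 * N + i] = p.phi * (g * mK - W[i]) / p.tau_K;
  }
  const double beta = betaAt(t, task, cycle_ms, speech_ms, p);
  out[3 * N] = beta * QV[sncL] - p.V_max * cl / (p.K_m + cl);
  out[3 * N + 1] = beta * QV[sncR] - p.V_max * cr / (p.K_m + cr);
}

}  // namespace

// [[Rcpp::export(name = ".neuralDriftCpp")]]
NumericVector neural_drift_cpp(double t, NumericVector y, NumericVector params,
                               NumericMatrix C, NumericVector aie,
                               int lmcL, int lmcR, int sncL, int sncR,
                               bool task, double cycle_ms, double speech_ms) {
  const Pars p = readPars(params);
  const int N = C.nrow();
  if (y.size() != 3 * N + 2) stop("state has length %d, expected %d", y.size(), 3 * N + 2);
  std::vector<double> yy(y.begin(), y.end()), out(y.size()), QV(N);
  evalDrift(t, yy, out, p, C, aie, lmcL, lmcR, sncL, sncR, task, cycle_ms,
            speech_ms, QV);
  return wrap(out);
}

// [[Rcpp::export(name = ".integrateModelCpp")]]
List integrate_model_cpp(NumericVector y0, double t0, double h, int nsteps,
                         int stride, std::string scheme, NumericVector params,
                         NumericMatrix C, NumericVector aie, NumericVector bvec,
                         int lmcL, int lmcR, int sncL, int sncR,
                         bool task, double cycle_ms, double speech_ms) {
  const Pars p = readPars(params);
  const int N = C.nrow();
  const int d = y0.size();
  if (d != 3 * N + 2) stop("state has length %d, expected %d", d, 3 * N + 2);
  if (nsteps % stride != 0) stop("nsteps must be a multiple of stride");
  const bool rk = (scheme == "rk15");
  if (!rk && scheme != "milstein") stop("unknown scheme '%s'", scheme.c_str());

  const int nrows = nsteps / stride + 1;
  NumericMatrix states(nrows, d);
  NumericVector times(nrows);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> a0(d), ap(d), am(d), yp(d), ym(d), QV(N);
  const double sqh = std::sqrt(h);
  const double s3 = std::sqrt(3.0);

  times[0] = t0;
  for (int i = 0; i < d; ++i) states(0, i) = y[i];

  int row = 1;
  for (int n = 0; n < nsteps; ++n) {
    const double t = t0 + n * h;
    const double u1 = norm_rand();
    const double u2 = norm_rand();
    const double dW = sqh * u1;
    const double dZ = 0.5 * h * sqh * (u1 + u2 / s3);
    evalDrift(t, y, a0, p, C, aie, lmcL, lmcR, sncL, sncR, task, cycle_ms,
              speech_ms, QV);
    if (rk) {
      for (int i = 0; i < d; ++i) {
        yp[i] = y[i] + a0[i] * h + bvec[i] * sqh;
        ym[i] = y[i] + a0[i] * h - bvec[i] * sqh;
      }
      evalDrift(t + h, yp, ap, p, C, aie, lmcL, lmcR, sncL, sncR, task,
                cycle_ms, speech_ms, QV);
      evalDrift(t + h, ym, am, p, C, aie, lmcL, lmcR, sncL, sncR, task,
                cycle_ms, speech_ms, QV);
      const double wp = h / 4.0 + dZ / (2.0 * sqh);
      const double wm = h / 4.0 - dZ / (2.0 * sqh);
      for (int i = 0; i < d; ++i)
        y[i] += bvec[i] * dW + 0.5 * h * a0[i] + wp * ap[i] + wm * am[i];
    } else {
      for (int i = 0; i < d; ++i) y[i] += a0[i] * h + bvec[i] * dW;
    }
    // discrete steps may undershoot zero dopamine; the continuous model cannot
    if (y[3 * N] < 0.0) y[3 * N] = 0.0;
    if (y[3 * N + 1] < 0.0) y[3 * N + 1] = 0.0;
    if ((n + 1) % stride == 0) {
      for (int i = 0; i < d; ++i) {
        if (!R_finite(y[i]))
          stop("integration diverged at step %d (t = %g ms), state component %d",
               n + 1, t + h, i + 1);
        states(row, i) = y[i];
      }
      times[row] = t0 + (n + 1) * h;
      ++row;
    }
  }
  return List::create(_["times"] = times, _["states"] = states);
}
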