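#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// SIR right-hand side in proportions of the total population:
//   ds/dt = -beta * s * i
//   di/dt =  beta * s * i - gamma * i
//   dr/dt =  gamma * i
// With this scaling R0 = beta / gamma and the early growth rate is
// r = beta - gamma (since s ~ 1 at the outset).
static inline void sir_rhs(double beta, double gamma, const double y[3],
                           double dy[3]) {
  const double inf = beta * y[0] * y[1];
  const double rec = gamma * y[1];
  dy[0] = -inf;
  dy[1] = inf - rec;
  dy[2] = rec;
}

// Dormand-Prince 5(4) coefficients.
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
// 4th-order embedded weights.
static const double E1 = 5179.0 / 57600, E3 = 7571.0 / 16695, E4 = 393.0 / 640,
                    E5 = -92097.0 / 339200, E6 = 187.0 / 2100, E7 = 1.0 / 40;

// Integrate the SIR system (proportions) and report (s, i, r) at each
// requested time. times must be non-decreasing; times[0] is the initial
// time at which (s0, i0, r0) hold. Returns an n x 3 matrix, or a matrix
// of NaN from the first failed row onward if the step size underflows.
// [[Rcpp::export(name = ".sir_integrate_cpp")]]
NumericMatrix sir_integrate_cpp(double beta, double gamma, double s0,
                                double i0, double r0, NumericVector times,
                                double rtol = 1e-8, double atol = 1e-10) {
  const int n = times.size();
  NumericMatrix out(n, 3);
  double y[3] = {s0, i0, r0};
  double t = times[0];
  out(0, 0) = y[0]; out(0, 1) = y[1]; out(0, 2) = y[2];

  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], ytmp[3], ynew[3];
  // Initial step: conservative fraction of the fastest time scale.
  const double rate = std::max(beta, gamma);
  double h = (rate > 0) ? std::min(0.1, 0.01 / rate) : 0.1;
  bool failed = false;
  long nsteps = 0;
  const long max_steps = 50000000L;

  for (int k = 1; k < n; ++k) {
    const double t_end = times[k];
    while (!failed && t < t_end) {
      if (++nsteps > max_steps) { failed = true; break; }
      double hs = std::min(h, t_end - t);
      sir_rhs(beta, gamma, y, k1);
      for (int j = 0; j < 3; ++j) ytmp[j] = y[j] + hs * A21 * k1[j];
      sir_rhs(beta, gamma, ytmp, k2);
      for (int j = 0; j < 3; ++j)
        ytmp[j] = y[j] + hs * (A31 * k1[j] + A32 * k2[j]);
      sir_rhs(beta, gamma, ytmp, k3);
      for (int j = 0; j < 3; ++j)
        ytmp[j] = y[j] + hs * (A41 * k1[j] + A42 * k2[j] + A43 * k3[j]);
      sir_rhs(beta, gamma, ytmp, k4);
      for (int j = 0; j < 3; ++j)
        ytmp[j] = y[j] + hs * (A51 * k1[j] + A52 * k2[j] + A53 * k3[j] +
                               A54 * k4[j]);
      sir_rhs(beta, gamma, ytmp, k5);
      for (int j = 0; j < 3; ++j)
        ytmp[j] = y[j] + hs * (A61 * k1[j] + A62 * k2[j] + A63 * k3[j] +
                               A64 * k4[j] + A65 * k5[j]);
      sir_rhs(beta, gamma, ytmp, k6);
      for (int j = 0; j < 3; ++j)
        ynew[j] = y[j] + hs * (B1 * k1[j] + B3 * k3[j] + B4 * k4[j] +
                               B5 * k5[j] + B6 * k6[j]);
      sir_rhs(beta, gamma, ynew, k7);

      double err = 0.0;
      for (int j = 0; j < 3; ++j) {
        const double y4 = y[j] + hs * (E1 * k1[j] + E3 * k3[j] + E4 * k4[j] +
                                       E5 * k5[j] + E6 * k6[j] + E7 * k7[j]);
        const double sc =
            atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
        const double e = (ynew[j] - y4) / sc;
        err += e * e;
      }
      err = std::sqrt(err / 3.0);

      if (!std::isfinite(err)) { failed = true; break; }
      if (err <= 1.0) {
        t += hs;
        for (int j = 0; j < 3; ++j) y[j] = ynew[j];
      }
      double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h = hs * fac;
      if (h < 1e-14) { failed = true; break; }
    }
    if (failed) {
      for (int kk = k; kk < n; ++kk)
        for (int j = 0; j < 3; ++j) out(kk, j) = NA_REAL;
      break;
    }
    out(k, 0) = y[0]; out(k, 1) = y[1]; out(k, 2) = y[2];
  }
  return out;
}

// Exact stochastic SIR via the Gillespie direct method. Reactions:
//   infection S + I -> 2I at rate beta * S * I / N
//   recovery  I -> R     at rate gamma * I
// where N = S0 + I0 (initially recovered population is zero), so that
// R0 = beta / gamma independent of N. Returns the infection event times
// in (0, t_max]; the I0 seed individuals are not events. Uses R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export(name = ".gillespie_sir_cpp")]]
NumericVector gillespie_sir_cpp(double beta, double gamma, int S0, int I0,
                                double t_max) {
  RNGScope scope;
  const double N = static_cast<double>(S0) + static_cast<double>(I0);
  long S = S0, I = I0;
  std::vector<double> events;
  events.reserve(static_cast<size_t>(S0 > 0 ? S0 : 1));
  double t = 0.0;
  while (I > 0 && t < t_max) {
    const double r_inf = (S > 0 && N > 0) ? beta * S * I / N : 0.0;
    const double r_rec = gamma * I;
    const double total = r_inf + r_rec;
    if (total <= 0) break;
    t += R::exp_rand() / total;
    if (t > t_max) break;
    if (R::unif_rand() * total < r_inf) {
      --S; ++I;
      events.push_back(t);
    } else {
      --I;
    }
  }
  return wrap(events);
}
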