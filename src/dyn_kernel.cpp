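#include <Rcpp.h>
using namespace Rcpp;

// State layout: 0 R_res, 1 CP, 2 CN, 3 D1, 4 D2, 5 T1, 6 T2.
// Deterministic field: Monod growth of every population, resource drawdown,
// and bilinear mass-action conjugation (CN -> T1 via D1+T1; CN,CP -> T2 via
// D2+T2). Donors are unchanged by conjugation.
static inline void deriv(const double *s, double *ds, double nu_max, double e,
                         double k, double gamma, bool conj_growth_scaled) {
  double psi = nu_max * s[0] / (k + s[0]);
  double g = conj_growth_scaled ? gamma * psi / nu_max : gamma;
  double tot = s[1] + s[2] + s[3] + s[4] + s[5] + s[6];
  double c1 = g * (s[3] + s[5]) * s[2]; // D1/T1 x CN -> T1
  double c2 = g * (s[4] + s[6]) * s[2]; // D2/T2 x CN -> T2
  double c3 = g * (s[4] + s[6]) * s[1]; // D2/T2 x CP -> T2
  ds[0] = -e * psi * tot;
  ds[1] = psi * s[1] - c3;
  ds[2] = psi * s[2] - c1 - c2;
  ds[3] = psi * s[3];
  ds[4] = psi * s[4];
  ds[5] = psi * s[5] + c1;
  ds[6] = psi * s[6] + c2 + c3;
}

// [[Rcpp::export]]
NumericMatrix dyn_kernel(NumericVector init, double nu_max, double e, double k,
                         double gamma, double mu, double nu_pl, double dt,
                         int n_steps, int rec_stride, double volume,
                         bool mut_per_division, bool conj_growth_scaled,
                         bool rk4) {
  double s[7], ds[7], k1[7], k2[7], k3[7], k4[7], tmp[7];
  for (int j = 0; j < 7; j++) s[j] = init[j];
  int n_rec = n_steps / rec_stride + (n_steps % rec_stride ? 2 : 1);
  NumericMatrix out(n_rec, 8);
  int row = 0;
  out(row, 0) = 0.0;
  for (int j = 0; j < 7; j++) out(row, j + 1) = s[j];
  row++;
  double inc[7];
  for (int i = 1; i <= n_steps; i++) {
    if (rk4) {
      deriv(s, k1, nu_max, e, k, gamma, conj_growth_scaled);
      for (int j = 0; j < 7; j++) tmp[j] = s[j] + 0.5 * dt * k1[j];
      deriv(tmp, k2, nu_max, e, k, gamma, conj_growth_scaled);
      for (int j = 0; j < 7; j++) tmp[j] = s[j] + 0.5 * dt * k2[j];
      deriv(tmp, k3, nu_max, e, k, gamma, conj_growth_scaled);
      for (int j = 0; j < 7; j++) tmp[j] = s[j] + dt * k3[j];
      deriv(tmp, k4, nu_max, e, k, gamma, conj_growth_scaled);
      for (int j = 0; j < 7; j++)
        inc[j] = dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    } else {
      deriv(s, ds, nu_max, e, k, gamma, conj_growth_scaled);
      for (int j = 0; j < 7; j++) inc[j] = dt * ds[j];
    }
    // at resource exhaustion, shorten the step so consumption stops at
    // R = 0 instead of clamping (which would create biomass from nothing)
    if (inc[0] < 0 && s[0] + inc[0] < 0) {
      double alpha = s[0] / (-inc[0]);
      for (int j = 0; j < 7; j++) inc[j] *= alpha;
    }
    for (int j = 0; j < 7; j++) {
      s[j] += inc[j];
      if (s[j] < 0) s[j] = 0; // negative-density guard
    }
    double psi = nu_max * s[0] / (k + s[0]);
    double ms = mut_per_division ? psi / nu_max : 1.0;
    double m1 = R::rpois(mu * s[1] * volume * dt * ms);
    double m2 = R::rpois(nu_pl * s[3] * volume * dt * ms);
    if (m1 > s[1] * volume) m1 = s[1] * volume;
    if (m2 > s[3] * volume) m2 = s[3] * volume;
    s[1] -= m1 / volume;
    s[2] += m1 / volume;
    s[3] -= m2 / volume;
    s[4] += m2 / volume;
    if (i % rec_stride == 0 || i == n_steps) {
      out(row, 0) = i * dt;
      for (int j = 0; j < 7; j++) out(row, j + 1) = s[j];
      row++;
    }
  }
  if (row < n_rec) out = out(Range(0, row - 1), Range(0, 7));
  return out;
}
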