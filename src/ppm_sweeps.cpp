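// Piecewise-parabolic (PPM) conservative sweeps of the transport module.
// Mirrors the reference R implementation in R/transport.R; the sweeps are
// the inner loop of every coupled run, hence compiled.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

inline void ppm_limit_1d(const double* c, int n, double* cL, double* cR,
                         double* dC, double* c6) {
  for (int i = 0; i < n; ++i) {
    double cl = cL[i], cr = cR[i], cc = c[i];
    if ((cr - cc) * (cc - cl) <= 0.0) { cl = cc; cr = cc; }
    double d = cr - cl;
    double s6 = 6.0 * cc - 3.0 * (cl + cr);
    if (d * s6 > d * d) cl = 3.0 * cc - 2.0 * cr;
    d = cr - cl;
    s6 = 6.0 * cc - 3.0 * (cl + cr);
    if (-(d * d) > d * s6) cr = 3.0 * cc - 2.0 * cl;
    cL[i] = cl; cR[i] = cr;
    dC[i] = cr - cl;
    c6[i] = 6.0 * cc - 3.0 * (cl + cr);
  }
}

inline double face_val_up(double cR, double dC, double c6, double sig) {
  return cR - 0.5 * sig * (dC - (1.0 - 2.0 * sig / 3.0) * c6);
}
inline double face_val_dn(double cL, double dC, double c6, double sig) {
  return cL + 0.5 * sig * (dC + (1.0 - 2.0 * sig / 3.0) * c6);
}

} // namespace

// [[Rcpp::export]]
List ppm_sweep_z_cpp(NumericMatrix cm, NumericMatrix Fz, NumericVector FzL,
                     NumericMatrix Vin, double dt) {
  const int Nz = cm.nrow(), Nr = cm.ncol();
  NumericMatrix cnew(Nz, Nr), Vout(Nz, Nr);
  double escaped = 0.0;
  std::vector<double> c(Nz), cL(Nz), cR(Nz), dC(Nz), c6(Nz), e(Nz - 1),
      adv(Nz + 1), V(Nz);
  for (int j = 0; j < Nr; ++j) {
    for (int i = 0; i < Nz; ++i) { c[i] = cm(i, j); V[i] = Vin(i, j); }
    // 4th-order edge values, 2-point at the ends; the parabola limiter
    // below monotonizes, and tiny residual undershoots are clipped by the
    // caller's positivity limiter
    for (int i = 0; i < Nz - 1; ++i) e[i] = 0.5 * (c[i] + c[i + 1]);
    for (int i = 1; i < Nz - 2; ++i) {
      e[i] = (7.0 * (c[i] + c[i + 1]) - (c[i - 1] + c[i + 2])) / 12.0;
    }
    cL[0] = c[0]; cR[Nz - 1] = c[Nz - 1];
    for (int i = 1; i < Nz; ++i) cL[i] = e[i - 1];
    for (int i = 0; i < Nz - 1; ++i) cR[i] = e[i];
    ppm_limit_1d(c.data(), Nz, cL.data(), cR.data(), dC.data(), c6.data());
    // interior faces
    for (int i = 0; i < Nz - 1; ++i) {
      double F = Fz(i, j);
      if (F >= 0.0) {
        double sig = std::min(F * dt / V[i], 1.0);
        adv[i + 1] = F * face_val_up(cR[i], dC[i], c6[i], sig);
      } else {
        double sig = std::min(-F * dt / V[i + 1], 1.0);
        adv[i + 1] = F * face_val_dn(cL[i + 1], dC[i + 1], c6[i + 1], sig);
      }
    }
    // open ends: first-order outflow, zero-concentration inflow
    double FR = Fz(Nz - 1, j), FL = FzL[j];
    adv[Nz] = (FR >= 0.0) ? FR * c[Nz - 1] : 0.0;
    adv[0] = (FL >= 0.0) ? 0.0 : FL * c[0];
    if (FR > 0.0) escaped += adv[Nz];
    if (FL < 0.0) escaped += -adv[0];
    for (int i = 0; i < Nz; ++i) {
      double Fright = Fz(i, j);
      double Fleft = (i == 0) ? FL : Fz(i - 1, j);
      double vo = V[i] - dt * (Fright - Fleft);
      cnew(i, j) = (c[i] * V[i] - dt * (adv[i + 1] - adv[i])) / vo;
      Vout(i, j) = vo;
    }
  }
  return List::create(_["c"] = cnew, _["V"] = Vout, _["escaped"] = escaped);
}

// [[Rcpp::export]]
List ppm_sweep_eta_cpp(NumericMatrix cm, NumericMatrix Fe, NumericMatrix Vin,
                       double dt, IntegerMatrix eidx, NumericMatrix ewt) {
  const int Nz = cm.nrow(), Nr = cm.ncol();
  NumericMatrix cnew(Nz, Nr), Vout(Nz, Nr);
  std::vector<double> c(Nr), cL(Nr), cR(Nr), dC(Nr), c6(Nr), e(Nr - 1),
      adv(Nr + 1), V(Nr);
  for (int i = 0; i < Nz; ++i) {
    for (int j = 0; j < Nr; ++j) { c[j] = cm(i, j); V[j] = Vin(i, j); }
    for (int j = 0; j < Nr - 1; ++j) {
      double v = 0.0;
      for (int k = 0; k < 4; ++k) v += ewt(j, k) * c[eidx(j, k) - 1];
      e[j] = v;
    }
    cL[0] = c[0]; cR[Nr - 1] = c[Nr - 1];
    for (int j = 1; j < Nr; ++j) cL[j] = e[j - 1];
    for (int j = 0; j < Nr - 1; ++j) cR[j] = e[j];
    ppm_limit_1d(c.data(), Nr, cL.data(), cR.data(), dC.data(), c6.data());
    adv[0] = 0.0; adv[Nr] = 0.0;      // axis and wall carry no flux
    for (int j = 0; j < Nr - 1; ++j) {
      double F = Fe(i, j);
      if (F >= 0.0) {
        double sig = std::min(F * dt / V[j], 1.0);
        adv[j + 1] = F * face_val_up(cR[j], dC[j], c6[j], sig);
      } else {
        double sig = std::min(-F * dt / V[j + 1], 1.0);
        adv[j + 1] = F * face_val_dn(cL[j + 1], dC[j + 1], c6[j + 1], sig);
      }
    }
    for (int j = 0; j < Nr; ++j) {
      double Fup = (j == Nr - 1) ? 0.0 : Fe(i, j);
      double Fdn = (j == 0) ? 0.0 : Fe(i, j - 1);
      double vo = V[j] - dt * (Fup - Fdn);
      cnew(i, j) = (c[j] * V[j] - dt * (adv[j + 1] - adv[j])) / vo;
      Vout(i, j) = vo;
    }
  }
  return List::create(_["c"] = cnew, _["V"] = Vout);
}
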