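#ifndef TEVARSIM_SMA_H
#define TEVARSIM_SMA_H

#include <cmath>

// 1D superelastic shape-memory-alloy law with flat transformation
// plateaus and linear kinetics in the driving stress.  Strain-driven,
// history carried by the martensite fraction xi and the transformation
// direction dir (+1 tension, -1 compression).  Compression plateau
// stresses are scaled by (1 + alpha).
struct SmaParams {
  double EA, EM, sSL, sEL, sSU, sEU, epsL, alpha;
};

inline double sma_modulus(double xi, const SmaParams &p) {
  return p.EA * p.EM / (p.EM + xi * (p.EA - p.EM));
}

// Solve E(x)*(a - x*epsL) = scale*(s0 + x*dS) for x; exact quadratic.
// a = strain measured along the transformation direction.
inline double sma_solve_xi(double a, double s0, double dS, double scale,
                           const SmaParams &p) {
  const double EA = p.EA, EM = p.EM;
  const double A = -scale * dS * (EA - EM);
  const double B = -EA * EM * p.epsL - scale * (s0 * (EA - EM) + dS * EM);
  const double C = EA * EM * a - scale * s0 * EM;
  double x;
  if (std::fabs(A) < 1e-12 * std::fabs(B)) {
    x = -C / B;
  } else {
    const double disc = B * B - 4.0 * A * C;
    const double sq = std::sqrt(disc > 0.0 ? disc : 0.0);
    // stable root selection: pick the root lying in [0, 1]
    const double q = -0.5 * (B + (B >= 0.0 ? sq : -sq));
    const double x1 = q / A, x2 = C / q;
    x = (x1 >= -1e-9 && x1 <= 1.0 + 1e-9) ? x1 : x2;
  }
  if (x < 0.0) x = 0.0;
  if (x > 1.0) x = 1.0;
  return x;
}

// One strain-driven update.  xi and dir are updated in place; returns stress.
inline double sma_point(double eps_new, double &xi, double &dir,
                        const SmaParams &p) {
  for (int pass = 0; pass < 2; ++pass) {
    double E = sma_modulus(xi, p);
    double s = (xi > 0.0) ? dir : ((eps_new >= 0.0) ? 1.0 : -1.0);
    if (s == 0.0) s = 1.0;
    double a = s * eps_new;            // strain along transformation direction
    double sig_drv = E * (a - xi * p.epsL); // driving (signed-along-s) stress
    double scale = (s > 0.0) ? 1.0 : (1.0 + p.alpha);
    double fwd = scale * (p.sSL + xi * (p.sEL - p.sSL));
    double rev = scale * (p.sEU + xi * (p.sSU - p.sEU));
    if (sig_drv > fwd && xi < 1.0) {
      xi = sma_solve_xi(a, p.sSL, p.sEL - p.sSL, scale, p);
      // beyond-plateau clamp: martensite elastic
      double sigm = sma_modulus(1.0, p) * (a - p.epsL);
      if (xi >= 1.0 - 1e-12 && sigm > scale * p.sEL) xi = 1.0;
      dir = s;
    } else if (sig_drv < rev && xi > 0.0) {
      xi = sma_solve_xi(a, p.sEU, p.sSU - p.sEU, scale, p);
      double sig0 = p.EA * a;
      if (xi <= 1e-12 && sig0 < scale * p.sEU) xi = 0.0;
      dir = s;
      if (xi == 0.0) {
        // fully reverted: re-examine as virgin material (sign may flip)
        continue;
      }
    }
    break;
  }
  double E = sma_modulus(xi, p);
  double s = (xi > 0.0) ? dir : ((eps_new >= 0.0) ? 1.0 : -1.0);
  return E * (eps_new - s * xi * p.epsL);
}

#endif
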