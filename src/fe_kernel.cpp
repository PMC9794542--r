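// Explicit-dynamics structural kernel: corotational two-node fibre beams
// (2 Gauss stations x 2x2 section fibres through the superelastic or
// linear law), constant-strain fabric membranes, node-to-rigid-surface
// penalty contact with Coulomb friction, beam self-contact, lumped mass
// with mass scaling, mass-proportional damping, central-difference
// time integration and kinetic-energy-based dynamic relaxation.
//
// Units: mm / N / MPa / tonne / s.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "sma.h"
using namespace Rcpp;

// ---------- small vector helpers ----------------------------------------
static inline void vset(double *a, double x, double y, double z) {
  a[0] = x; a[1] = y; a[2] = z;
}
static inline void vcopy(double *a, const double *b) {
  a[0] = b[0]; a[1] = b[1]; a[2] = b[2];
}
static inline double vdot(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(double *o, const double *a, const double *b) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vnorm(const double *a) { return std::sqrt(vdot(a, a)); }
static inline void vscale(double *a, double s) { a[0]*=s; a[1]*=s; a[2]*=s; }
static inline void vaxpy(double *o, double s, const double *a) {
  o[0] += s * a[0]; o[1] += s * a[1]; o[2] += s * a[2];
}

// quaternion (w,x,y,z) -> rotation matrix (column major R[3*c + r])
static inline void quat_to_mat(const double *q, double *R) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[3] = 2 * (x * y - w * z); R[6] = 2 * (x * z + w * y);
  R[1] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[7] = 2 * (y * z - w * x);
  R[2] = 2 * (x * z - w * y); R[5] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}
// q <- dq(omega*dt) * q, normalized
static inline void quat_rotate(double *q, const double *w, double dt) {
  double ax = w[0] * dt, ay = w[1] * dt, az = w[2] * dt;
  double th = std::sqrt(ax * ax + ay * ay + az * az);
  double dw = 1.0, f = 0.5;
  if (th > 1e-12) { dw = std::cos(th / 2); f = std::sin(th / 2) / th; }
  double dx = ax * f, dy = ay * f, dz = az * f;
  double nw = dw * q[0] - dx * q[1] - dy * q[2] - dz * q[3];
  double nx = dw * q[1] + dx * q[0] + dy * q[3] - dz * q[2];
  double ny = dw * q[2] - dx * q[3] + dy * q[0] + dz * q[1];
  double nz = dw * q[3] + dx * q[2] - dy * q[1] + dz * q[0];
  double n = std::sqrt(nw * nw + nx * nx + ny * ny + nz * nz);
  q[0] = nw / n; q[1] = nx / n; q[2] = ny / n; q[3] = nz / n;
}

// ---------- model unpacked into plain C structures -----------------------
struct BeamModel {
  int m;                       // elements
  std::vector<int> na, nb;
  std::vector<double> r;       // section radius
  std::vector<int> mat;        // 0 = sma, 1 = linear
  std::vector<double> Elin;    // modulus for linear elements
  SmaParams sma;
  double nu;                   // for elastic shear modulus
  std::vector<double> L0;
  std::vector<double> E0;      // 9 per element, initial triads (col major)
};
struct MemModel {
  int k;
  std::vector<int> t1, t2, t3;
  std::vector<double> DmInv;   // 4 per tri (2x2 inverse ref edge matrix)
  std::vector<double> Aref;
  double thick, Ef, nuf, cfac; // fabric law
};

struct Surface {
  int kind;                    // 0 plane, 1 tube (inner)
  double n0[3];                // plane normal (toward allowed side)
  double p_from[3], p_to[3];   // plane point
  std::vector<double> P;       // tube centerline points (3*np)
  std::vector<double> P_to;    // morph target centerline (empty = static)
  std::vector<double> P_cur;   // interpolated centerline at current ramp
  std::vector<double> S;       // cumulative arc length
  int np;
  bool morph;
  double R_from, R_to;
  double win_from[2], win_to[2];
  double mu, k_scale;
  // friction anchors
  std::vector<double> anchor;  // 3 per node
  std::vector<unsigned char> active;
  std::vector<int> hint;       // last closest centerline segment per node
};

// closest point on polyline; returns arc length s, point c, tangent tg.
// hint (in/out) restricts the search to nearby segments when >= 0.
static void polyline_closest(const Surface &sf, const double *x,
                             double &s, double *c, double *tg,
                             int *hint = 0) {
  double best = 1e300;
  int i0 = 0, i1 = sf.np - 1, ibest = 0;
  if (hint && *hint >= 0) {
    i0 = std::max(0, *hint - 3);
    i1 = std::min(sf.np - 1, *hint + 4);
  }
  for (int i = i0; i < i1; ++i) {
    const double *a = &sf.P[3 * i], *b = &sf.P[3 * (i + 1)];
    double ab[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
    double L2 = vdot(ab, ab);
    double t = 0.0;
    if (L2 > 0) {
      double ax[3] = { x[0] - a[0], x[1] - a[1], x[2] - a[2] };
      t = vdot(ax, ab) / L2;
      if (t < 0) t = 0; if (t > 1) t = 1;
    }
    double p[3] = { a[0] + t * ab[0], a[1] + t * ab[1], a[2] + t * ab[2] };
    double d2 = (x[0]-p[0])*(x[0]-p[0]) + (x[1]-p[1])*(x[1]-p[1]) + (x[2]-p[2])*(x[2]-p[2]);
    if (d2 < best) {
      best = d2;
      ibest = i;
      s = sf.S[i] + t * (sf.S[i + 1] - sf.S[i]);
      vcopy(c, p);
      double Ln = std::sqrt(L2);
      if (Ln > 0) { tg[0] = ab[0]/Ln; tg[1] = ab[1]/Ln; tg[2] = ab[2]/Ln; }
      else vset(tg, 0, 0, 1);
    }
  }
  if (hint) *hint = ibest;
}

// segment-segment closest points (s,t in [0,1])
static double seg_seg_dist(const double *p1, const double *q1,
                           const double *p2, const double *q2,
                           double &s, double &t) {
  double d1[3] = { q1[0]-p1[0], q1[1]-p1[1], q1[2]-p1[2] };
  double d2[3] = { q2[0]-p2[0], q2[1]-p2[1], q2[2]-p2[2] };
  double r[3] = { p1[0]-p2[0], p1[1]-p2[1], p1[2]-p2[2] };
  double a = vdot(d1, d1), e = vdot(d2, d2), f = vdot(d2, r);
  double c2 = vdot(d1, r), b = vdot(d1, d2);
  double denom = a * e - b * b;
  s = (denom > 1e-14) ? (b * f - c2 * e) / denom : 0.0;
  if (s < 0) s = 0; if (s > 1) s = 1;
  t = (e > 1e-14) ? (b * s + f) / e : 0.0;
  if (t < 0) { t = 0; s = (a > 1e-14) ? -c2 / a : 0.0; }
  else if (t > 1) { t = 1; s = (a > 1e-14) ? (b - c2) / a : 0.0; }
  if (s < 0) s = 0; if (s > 1) s = 1;
  double c1[3] = { p1[0]+s*d1[0], p1[1]+s*d1[1], p1[2]+s*d1[2] };
  double c3[3] = { p2[0]+t*d2[0], p2[1]+t*d2[1], p2[2]+t*d2[2] };
  double d[3] = { c1[0]-c3[0], c1[1]-c3[1], c1[2]-c3[2] };
  return vnorm(d);
}

static BeamModel unpack_beam(const List &model) {
  BeamModel B;
  IntegerMatrix conn = model["beam_conn"];
  NumericVector r = model["beam_r"];
  IntegerVector mat = model["beam_mat"];
  NumericVector El = model["beam_E"];
  NumericVector sp = model["sma_params"];
  B.m = conn.nrow();
  B.na.resize(B.m); B.nb.resize(B.m);
  B.r.resize(B.m); B.mat.resize(B.m); B.Elin.resize(B.m);
  for (int e = 0; e < B.m; ++e) {
    B.na[e] = conn(e, 0) - 1; B.nb[e] = conn(e, 1) - 1;
    B.r[e] = r[e]; B.mat[e] = mat[e]; B.Elin[e] = El[e];
  }
  B.sma.EA = sp["E_A"]; B.sma.EM = sp["E_M"];
  B.sma.sSL = sp["sig_SL"]; B.sma.sEL = sp["sig_EL"];
  B.sma.sSU = sp["sig_SU"]; B.sma.sEU = sp["sig_EU"];
  B.sma.epsL = sp["eps_L"]; B.sma.alpha = sp["alpha"];
  B.nu = as<double>(model["beam_nu"]);
  return B;
}

static MemModel unpack_mem(const List &model) {
  MemModel M;
  if (Rf_isNull(model["mem_tris"])) { M.k = 0; return M; }
  IntegerMatrix t = model["mem_tris"];
  M.k = t.nrow();
  M.t1.resize(M.k); M.t2.resize(M.k); M.t3.resize(M.k);
  for (int i = 0; i < M.k; ++i) {
    M.t1[i] = t(i, 0) - 1; M.t2[i] = t(i, 1) - 1; M.t3[i] = t(i, 2) - 1;
  }
  M.thick = as<double>(model["mem_thick"]);
  NumericVector fb = model["fabric"];
  M.Ef = fb["E_long"]; M.nuf = fb["nu"]; M.cfac = fb["factor"];
  return M;
}

// beam reference triads and lengths from coordinates
static void beam_reference(const BeamModel &B, const NumericMatrix &x,
                           std::vector<double> &L0, std::vector<double> &E0) {
  L0.resize(B.m); E0.resize(9 * B.m);
  for (int e = 0; e < B.m; ++e) {
    int a = B.na[e], b = B.nb[e];
    double t[3] = { x(b,0)-x(a,0), x(b,1)-x(a,1), x(b,2)-x(a,2) };
    double L = vnorm(t);
    L0[e] = L;
    double e1[3] = { t[0]/L, t[1]/L, t[2]/L };
    double up[3] = { 0, 0, 1 };
    if (std::fabs(vdot(e1, up)) > 0.95) vset(up, 1, 0, 0);
    double e3[3]; vcross(e3, e1, up);
    double n3 = vnorm(e3); vscale(e3, 1.0 / n3);
    double e2[3]; vcross(e2, e3, e1);
    double *E = &E0[9 * e];
    E[0]=e1[0]; E[1]=e1[1]; E[2]=e1[2];
    E[3]=e2[0]; E[4]=e2[1]; E[5]=e2[2];
    E[6]=e3[0]; E[7]=e3[1]; E[8]=e3[2];
  }
}

// membrane reference geometry
static void mem_reference(const MemModel &M, const NumericMatrix &x,
                          std::vector<double> &DmInv, std::vector<double> &Aref) {
  DmInv.resize(4 * M.k); Aref.resize(M.k);
  for (int i = 0; i < M.k; ++i) {
    int a = M.t1[i], b = M.t2[i], c = M.t3[i];
    double u[3] = { x(b,0)-x(a,0), x(b,1)-x(a,1), x(b,2)-x(a,2) };
    double v[3] = { x(c,0)-x(a,0), x(c,1)-x(a,1), x(c,2)-x(a,2) };
    double n[3]; vcross(n, u, v);
    double A2 = vnorm(n);
    Aref[i] = 0.5 * A2;
    double lu = vnorm(u);
    double e1[3] = { u[0]/lu, u[1]/lu, u[2]/lu };
    double e2[3]; vcross(e2, n, e1); double l2 = vnorm(e2); vscale(e2, 1.0/l2);
    // ref edge matrix Dm = [[lu, v.e1],[0, v.e2]]
    double d11 = lu, d12 = vdot(v, e1), d22 = vdot(v, e2);
    double det = d11 * d22;
    double *Di = &DmInv[4 * i];
    Di[0] = d22 / det; Di[1] = 0.0;
    Di[2] = -d12 / det; Di[3] = d11 / det;
  }
}

// ---------- internal force evaluations -----------------------------------
// Beam forces; updates fibre history in place when `commit` is true.
// f (3n), mom (3n) are accumulated (+= internal force, i.e. dU/dx).
static void beam_forces(const BeamModel &B,
                        const std::vector<double> &L0,
                        const std::vector<double> &E0,
                        const NumericMatrix &x, const NumericMatrix &q,
                        std::vector<double> &fib_eps,
                        std::vector<double> &fib_xi,
                        std::vector<double> &fib_dir,
                        std::vector<double> &fib_sig,
                        std::vector<double> &tor_en,
                        bool commit, double *f, double *mom,
                        double *ie_inc, double *max_eps,
                        double visc = 0.0, double *d_visc = 0) {
  const double gx[2] = { 0.5 - 0.5 / std::sqrt(3.0), 0.5 + 0.5 / std::sqrt(3.0) };
  const double gw[2] = { 0.5, 0.5 };
  // fibre offsets at (+-c, +-c), c = r/2 reproduces EA and EI exactly
  const double fy[4] = { 1, 1, -1, -1 };
  const double fz[4] = { 1, -1, 1, -1 };
  for (int e = 0; e < B.m; ++e) {
    int a = B.na[e], b = B.nb[e];
    double t[3] = { x(b,0)-x(a,0), x(b,1)-x(a,1), x(b,2)-x(a,2) };
    double Lc = vnorm(t);
    if (Lc < 1e-12) Rcpp::stop("zero-length beam element");
    double e1[3] = { t[0]/Lc, t[1]/Lc, t[2]/Lc };
    double qa[4] = { q(a,0), q(a,1), q(a,2), q(a,3) };
    double qb[4] = { q(b,0), q(b,1), q(b,2), q(b,3) };
    double Ra[9], Rb[9];
    quat_to_mat(qa, Ra);
    quat_to_mat(qb, Rb);
    const double *E0e = &E0[9 * e];
    // rotate initial e2 by mean rotation
    double r2[3];
    for (int i = 0; i < 3; ++i)
      r2[i] = 0.5 * ((Ra[0+i]*E0e[3] + Ra[3+i]*E0e[4] + Ra[6+i]*E0e[5]) +
                     (Rb[0+i]*E0e[3] + Rb[3+i]*E0e[4] + Rb[6+i]*E0e[5]));
    double e3[3]; vcross(e3, e1, r2);
    double n3 = vnorm(e3);
    if (n3 < 1e-12) { // fallback
      double up[3] = {0,0,1};
      if (std::fabs(vdot(e1, up)) > 0.95) vset(up,1,0,0);
      vcross(e3, e1, up); n3 = vnorm(e3);
    }
    vscale(e3, 1.0 / n3);
    double e2[3]; vcross(e2, e3, e1);
    // local rotations theta_i = axial(E^T R_i E0)
    double th[2][3];
    for (int nn = 0; nn < 2; ++nn) {
      const double *R = nn == 0 ? Ra : Rb;
      double RE[9]; // R * E0
      for (int cc = 0; cc < 3; ++cc)
        for (int rr = 0; rr < 3; ++rr)
          RE[3*cc+rr] = R[0+rr]*E0e[3*cc+0] + R[3+rr]*E0e[3*cc+1] + R[6+rr]*E0e[3*cc+2];
      double Lm[9]; // E^T * RE
      const double *Ecols[3] = { e1, e2, e3 };
      for (int cc = 0; cc < 3; ++cc)
        for (int rr = 0; rr < 3; ++rr)
          Lm[3*cc+rr] = vdot(Ecols[rr], &RE[3*cc]);
      th[nn][0] = 0.5 * (Lm[3*1+2] - Lm[3*2+1]);
      th[nn][1] = 0.5 * (Lm[3*2+0] - Lm[3*0+2]);
      th[nn][2] = 0.5 * (Lm[3*0+1] - Lm[3*1+0]);
    }
    double L0e = L0[e];
    double eps0 = (Lc - L0e) / L0e;
    double rr = B.r[e];
    double A = M_PI * rr * rr;
    double Af = A / 4.0, c = rr / 2.0;
    double twist = (th[1][0] - th[0][0]) / L0e;
    double Emod = (B.mat[e] == 0) ? B.sma.EA : B.Elin[e];
    double G = Emod / (2.0 * (1.0 + B.nu));
    double J = M_PI * rr * rr * rr * rr / 2.0;
    double T = G * J * twist;
    double N = 0.0, ma2 = 0.0, mb2 = 0.0, ma3 = 0.0, mb3 = 0.0;
    for (int g = 0; g < 2; ++g) {
      double xi = gx[g];
      double B1 = (-4.0 + 6.0 * xi) / L0e;
      double B2 = (-2.0 + 6.0 * xi) / L0e;
      double k2 = B1 * th[0][1] + B2 * th[1][1];
      double k3 = B1 * th[0][2] + B2 * th[1][2];
      double M2 = 0.0, M3 = 0.0, Ng = 0.0;
      for (int fb = 0; fb < 4; ++fb) {
        int id = 8 * e + 4 * g + fb;
        double eps = eps0 + c * fz[fb] * k2 - c * fy[fb] * k3;
        double deps = eps - fib_eps[id];
        double sig;
        if (B.mat[e] == 0) {
          double xs = fib_xi[id], ds = fib_dir[id];
          sig = sma_point(eps, xs, ds, B.sma);
          if (commit) {
            *ie_inc += 0.5 * (sig + fib_sig[id]) * deps * Af * L0e * gw[g];
            fib_xi[id] = xs; fib_dir[id] = ds;
            fib_sig[id] = sig; fib_eps[id] = eps;
          }
        } else {
          sig = B.Elin[e] * eps;
          if (commit) {
            *ie_inc += 0.5 * (sig + fib_sig[id]) * deps * Af * L0e * gw[g];
            fib_sig[id] = sig; fib_eps[id] = eps;
          }
        }
        if (std::fabs(eps) > *max_eps) *max_eps = std::fabs(eps);
        // stiffness-proportional viscosity damps element-local modes
        double sv = visc * Emod * deps;
        if (d_visc) *d_visc += sv * deps * Af * L0e * gw[g];
        double sig_t = sig + sv;
        Ng += Af * sig_t;
        M2 += Af * sig_t * c * fz[fb];
        M3 += Af * sig_t * c * fy[fb];
      }
      N += gw[g] * Ng;
      ma2 += gw[g] * L0e * M2 * B1;
      mb2 += gw[g] * L0e * M2 * B2;
      ma3 += gw[g] * L0e * (-M3) * B1;
      mb3 += gw[g] * L0e * (-M3) * B2;
    }
    if (commit) {
      double en = 0.5 * T * twist * L0e;  // elastic torsion energy
      *ie_inc += en - tor_en[e];
      tor_en[e] = en;
    }
    double ma1 = -T, mb1 = T;
    // equilibrium shear from moments
    double V2 = (ma3 + mb3) / Lc;
    double V3 = -(ma2 + mb2) / Lc;
    // internal nodal forces (dU/dx): node a gets -N e1 + V..., opposite on b
    double fa[3] = { 0, 0, 0 };
    vaxpy(fa, -N, e1); vaxpy(fa, V2, e2); vaxpy(fa, V3, e3);
    for (int i = 0; i < 3; ++i) {
      f[3*a+i] -= fa[i];            // f holds force ON node (= -dU/dx)
      f[3*b+i] += fa[i];
      mom[3*a+i] -= ma1*e1[i] + ma2*e2[i] + ma3*e3[i];
      mom[3*b+i] -= mb1*e1[i] + mb2*e2[i] + mb3*e3[i];
    }
  }
}

// fabric / membrane forces. Returns min area ratio and max tensile strain.
static void mem_forces(const MemModel &M,
                       const std::vector<double> &DmInv,
                       const std::vector<double> &Aref,
                       const NumericMatrix &x,
                       double *f, double *ie_inc,
                       std::vector<double> &mem_en,
                       std::vector<double> &mem_eps,
                       double *minJ, double *max_tens,
                       double visc = 0.0, double *d_visc = 0,
                       bool commit = true) {
  for (int i = 0; i < M.k; ++i) {
    int a = M.t1[i], b = M.t2[i], c = M.t3[i];
    double u[3] = { x(b,0)-x(a,0), x(b,1)-x(a,1), x(b,2)-x(a,2) };
    double v[3] = { x(c,0)-x(a,0), x(c,1)-x(a,1), x(c,2)-x(a,2) };
    double n[3]; vcross(n, u, v);
    double A2 = vnorm(n);
    if (A2 < 1e-14) { *minJ = 0.0; continue; }
    double lu = vnorm(u);
    double e1[3] = { u[0]/lu, u[1]/lu, u[2]/lu };
    double e2[3]; vcross(e2, n, e1); double l2 = vnorm(e2); vscale(e2, 1.0/l2);
    // current edge matrix in local frame
    double d11 = lu, d12 = vdot(v, e1), d22 = vdot(v, e2);
    const double *Di = &DmInv[4 * i];
    // F = Dc * DmInv  (2x2)
    double F11 = d11 * Di[0] + d12 * Di[1];
    double F12 = d11 * Di[2] + d12 * Di[3];
    double F21 = 0.0 * Di[0] + d22 * Di[1];
    double F22 = 0.0 * Di[2] + d22 * Di[3];
    double J = F11 * F22 - F12 * F21;
    if (J < *minJ) *minJ = J;
    // small-strain (Biot-like) corotational strain
    double e11 = F11 - 1.0, e22 = F22 - 1.0, g12 = F12 + F21;
    // plane-stress isotropic + compressive principal scaling
    double c1 = M.Ef / (1.0 - M.nuf * M.nuf);
    double s11 = c1 * (e11 + M.nuf * e22);
    double s22 = c1 * (e22 + M.nuf * e11);
    double s12 = c1 * (1.0 - M.nuf) / 2.0 * g12;
    double mm = 0.5 * (s11 + s22), dd = 0.5 * (s11 - s22);
    double rr = std::sqrt(dd * dd + s12 * s12);
    double p1 = mm + rr, p2 = mm - rr;
    double thp = 0.5 * std::atan2(2.0 * s12, s11 - s22);
    if (p1 < 0) p1 *= M.cfac;
    if (p2 < 0) p2 *= M.cfac;
    double ct = std::cos(thp), st = std::sin(thp);
    s11 = p1 * ct * ct + p2 * st * st;
    s22 = p1 * st * st + p2 * ct * ct;
    s12 = (p1 - p2) * st * ct;
    // principal strain for fatal checks
    double em = 0.5 * (e11 + e22), ed = 0.5 * (e11 - e22);
    double er = std::sqrt(ed * ed + 0.25 * g12 * g12);
    double emax = em + er;
    if (emax > *max_tens) *max_tens = emax;
    // stiffness-proportional viscosity on the strain rate
    double de11 = e11 - mem_eps[3*i], de22 = e22 - mem_eps[3*i+1],
           dg12 = g12 - mem_eps[3*i+2];
    double cv = visc * c1;
    s11 += cv * (de11 + M.nuf * de22);
    s22 += cv * (de22 + M.nuf * de11);
    s12 += cv * (1.0 - M.nuf) / 2.0 * dg12;
    if (d_visc)
      *d_visc += cv * (de11 * de11 + de22 * de22 +
                       (1.0 - M.nuf) / 2.0 * dg12 * dg12) * M.thick * Aref[i];
    if (commit) {
      mem_eps[3*i] = e11; mem_eps[3*i+1] = e22; mem_eps[3*i+2] = g12;
    }
    // nodal forces: P = t*Aref * sigma * F^{-T}-free small-strain form:
    // f_loc(node) = t*Aref * sigma . gradN
    // gradN rows from DmInv: gradN2 = (Di[0], Di[2]); gradN3 = (Di[1], Di[3])
    double g2x = Di[0], g2y = Di[2], g3x = Di[1], g3y = Di[3];
    double tA = M.thick * Aref[i];
    double fb2[2] = { tA * (s11 * g2x + s12 * g2y), tA * (s12 * g2x + s22 * g2y) };
    double fb3[2] = { tA * (s11 * g3x + s12 * g3y), tA * (s12 * g3x + s22 * g3y) };
    double fb1[2] = { -fb2[0] - fb3[0], -fb2[1] - fb3[1] };
    // energy increment: elastic strain energy (viscous part excluded)
    double en = 0.5 * tA * ((s11 - cv * (de11 + M.nuf * de22)) * e11 +
                            (s22 - cv * (de22 + M.nuf * de11)) * e22 +
                            (s12 - cv * (1.0 - M.nuf) / 2.0 * dg12) * g12);
    *ie_inc += en - mem_en[i];
    mem_en[i] = en;
    // map to 3D (force ON node = -f_loc)
    for (int d = 0; d < 3; ++d) {
      f[3*a+d] -= fb1[0] * e1[d] + fb1[1] * e2[d];
      f[3*b+d] -= fb2[0] * e1[d] + fb2[1] * e2[d];
      f[3*c+d] -= fb3[0] * e1[d] + fb3[1] * e2[d];
    }
  }
}

// ---------- exported single evaluations for unit tests -------------------
// [[Rcpp::export]]
List beam_forces_cpp(List model, NumericMatrix x, NumericMatrix q,
                     NumericMatrix x_ref) {
  BeamModel B = unpack_beam(model);
  std::vector<double> L0, E0;
  beam_reference(B, x_ref, L0, E0);
  int n = x.nrow();
  std::vector<double> f(3 * n, 0.0), mom(3 * n, 0.0);
  std::vector<double> fe(8 * B.m, 0.0), fx(8 * B.m, 0.0),
      fd(8 * B.m, 1.0), fs(8 * B.m, 0.0), te(B.m, 0.0);
  double ie = 0, me = 0;
  beam_forces(B, L0, E0, x, q, fe, fx, fd, fs, te, true, f.data(), mom.data(),
              &ie, &me);
  NumericMatrix F(n, 3), Mo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { F(i,d) = f[3*i+d]; Mo(i,d) = mom[3*i+d]; }
  return List::create(_["f"] = F, _["mom"] = Mo, _["max_eps"] = me,
                      _["fib_sig"] = NumericVector(fs.begin(), fs.end()),
                      _["fib_eps"] = NumericVector(fe.begin(), fe.end()));
}

// [[Rcpp::export]]
List membrane_forces_cpp(List model, NumericMatrix x, NumericMatrix x_ref) {
  MemModel M = unpack_mem(model);
  std::vector<double> DmInv, Aref;
  mem_reference(M, x_ref, DmInv, Aref);
  int n = x.nrow();
  std::vector<double> f(3 * n, 0.0), men(M.k, 0.0), meps(3 * M.k, 0.0);
  double ie = 0, minJ = 1e300, mt = -1e300;
  mem_forces(M, DmInv, Aref, x, f.data(), &ie, men, meps, &minJ, &mt);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) F(i,d) = f[3*i+d];
  return List::create(_["f"] = F, _["min_J"] = minJ, _["max_tensile"] = mt,
                      _["ie"] = ie);
}

// [[Rcpp::export]]
List contact_eval_cpp(NumericMatrix x, List surface, double k_pen) {
  int n = x.nrow();
  Surface sf;
  std::string kind = as<std::string>(surface["kind"]);
  NumericMatrix fr(n, 3);
  NumericVector gap(n), fn(n);
  if (kind == "plane") {
    NumericVector nn = surface["normal"], pp = surface["point"];
    for (int i = 0; i < n; ++i) {
      double d = (x(i,0)-pp[0])*nn[0] + (x(i,1)-pp[1])*nn[1] + (x(i,2)-pp[2])*nn[2];
      if (d < 0) {
        gap[i] = -d; fn[i] = k_pen * (-d);
        for (int c = 0; c < 3; ++c) fr(i,c) = fn[i] * nn[c];
      }
    }
  } else { // tube (inner)
    NumericMatrix P = surface["centerline"];
    double R = as<double>(surface["radius"]);
    sf.np = P.nrow();
    sf.P.resize(3 * sf.np); sf.S.resize(sf.np);
    sf.S[0] = 0;
    for (int i = 0; i < sf.np; ++i) {
      for (int c = 0; c < 3; ++c) sf.P[3*i+c] = P(i, c);
      if (i > 0) {
        double d[3] = { P(i,0)-P(i-1,0), P(i,1)-P(i-1,1), P(i,2)-P(i-1,2) };
        sf.S[i] = sf.S[i-1] + vnorm(d);
      }
    }
    for (int i = 0; i < n; ++i) {
      double xx[3] = { x(i,0), x(i,1), x(i,2) }, s, cpt[3], tg[3];
      polyline_closest(sf, xx, s, cpt, tg);
      double rho[3] = { xx[0]-cpt[0], xx[1]-cpt[1], xx[2]-cpt[2] };
      double rn = vdot(rho, tg);
      vaxpy(rho, -rn, tg);
      double r = vnorm(rho);
      if (r > R) {
        gap[i] = r - R; fn[i] = k_pen * gap[i];
        for (int c = 0; c < 3; ++c) fr(i,c) = -fn[i] * rho[c] / r;
      }
    }
  }
  return List::create(_["f"] = fr, _["gap"] = gap, _["fn"] = fn);
}

// [[Rcpp::export]]
double min_strut_distance_cpp(NumericMatrix x, IntegerMatrix conn, int skip) {
  int m = conn.nrow();
  double best = 1e300;
  for (int e = 0; e < m; ++e) {
    for (int e2 = e + 1; e2 < m; ++e2) {
      int sep = std::min(std::abs(e2 - e), m - std::abs(e2 - e));
      if (sep <= skip) continue;
      double p1[3] = { x(conn(e,0)-1,0), x(conn(e,0)-1,1), x(conn(e,0)-1,2) };
      double q1[3] = { x(conn(e,1)-1,0), x(conn(e,1)-1,1), x(conn(e,1)-1,2) };
      double p2[3] = { x(conn(e2,0)-1,0), x(conn(e2,0)-1,1), x(conn(e2,0)-1,2) };
      double q2[3] = { x(conn(e2,1)-1,0), x(conn(e2,1)-1,1), x(conn(e2,1)-1,2) };
      double s, t;
      double d = seg_seg_dist(p1, q1, p2, q2, s, t);
      if (d < best) best = d;
    }
  }
  return best;
}

// ---------- state initialisation -----------------------------------------
// [[Rcpp::export]]
List fe_init_state_cpp(List model, double dt, bool mass_scaling) {
  NumericMatrix x0 = model["x0"];
  int n = x0.nrow();
  BeamModel B = unpack_beam(model);
  MemModel M = unpack_mem(model);
  std::vector<double> L0, E0, DmInv, Aref;
  beam_reference(B, x0, L0, E0);
  mem_reference(M, x0, DmInv, Aref);
  double rho_b = as<double>(model["beam_rho"]);
  double rho_m = M.k ? as<double>(model["mem_rho"]) : 0.0;
  std::vector<double> mass(n, 0.0), inr(n, 0.0);
  double m_phys_tot = 0.0;
  for (int e = 0; e < B.m; ++e) {
    double A = M_PI * B.r[e] * B.r[e];
    double me = rho_b * A * L0[e];
    mass[B.na[e]] += me / 2; mass[B.nb[e]] += me / 2;
    double Ie = me / 2 * (L0[e] * L0[e] / 12.0 + B.r[e] * B.r[e] / 4.0);
    inr[B.na[e]] += Ie; inr[B.nb[e]] += Ie;
    m_phys_tot += me;
  }
  for (int i = 0; i < M.k; ++i) {
    double me = rho_m * Aref[i] * M.thick;
    mass[M.t1[i]] += me / 3; mass[M.t2[i]] += me / 3; mass[M.t3[i]] += me / 3;
    m_phys_tot += me;
  }
  // mass scaling for the target timestep: m >= k dt^2 per attached element
  double added = 0.0;
  if (mass_scaling) {
    std::vector<double> mreq(n, 0.0), ireq(n, 0.0);
    for (int e = 0; e < B.m; ++e) {
      double A = M_PI * B.r[e] * B.r[e];
      double Emod = (B.mat[e] == 0) ? B.sma.EA : B.Elin[e];
      double I = M_PI * std::pow(B.r[e], 4) / 4.0;
      double kt = std::max(Emod * A / L0[e],
                           12.0 * Emod * I / std::pow(L0[e], 3));
      double kr = std::max(4.0 * Emod * I / L0[e],
                           Emod / (2.0 * (1.0 + B.nu)) * M_PI * std::pow(B.r[e], 4) / 2.0 / L0[e]);
      // stiffness contributions of attached elements add up at a node;
      // factor 4 keeps coupled bending/rotation modes inside the
      // central-difference stability limit
      double mr = 4.0 * kt * dt * dt, ir = 4.0 * kr * dt * dt;
      mreq[B.na[e]] += mr; mreq[B.nb[e]] += mr;
      ireq[B.na[e]] += ir; ireq[B.nb[e]] += ir;
    }
    for (int i = 0; i < M.k; ++i) {
      // CST in-plane stiffness scale ~ E' t (independent of element size)
      double km = M.Ef / (1.0 - M.nuf * M.nuf) * M.thick * 2.0;
      // generous margin: the fabric stiffens geometrically under the
      // large stretches of crimp/springback and the graft's inertia is
      // immaterial for the quasi-static protocols
      double mr = 16.0 * km * dt * dt;
      int nd[3] = { M.t1[i], M.t2[i], M.t3[i] };
      for (int j = 0; j < 3; ++j) mreq[nd[j]] += mr;
    }
    for (int i = 0; i < n; ++i) {
      if (mass[i] < mreq[i]) { added += mreq[i] - mass[i]; mass[i] = mreq[i]; }
      if (inr[i] < ireq[i]) inr[i] = ireq[i];
    }
  }
  NumericMatrix x = clone(x0), v(n, 3), w(n, 3);
  NumericMatrix q(n, 4);
  for (int i = 0; i < n; ++i) q(i, 0) = 1.0;
  List st = List::create(
    _["x"] = x, _["v"] = v, _["q"] = q, _["w"] = w,
    _["mass"] = NumericVector(mass.begin(), mass.end()),
    _["inertia"] = NumericVector(inr.begin(), inr.end()),
    _["L0"] = NumericVector(L0.begin(), L0.end()),
    _["E0"] = NumericVector(E0.begin(), E0.end()),
    _["DmInv"] = NumericVector(DmInv.begin(), DmInv.end()),
    _["Aref"] = NumericVector(Aref.begin(), Aref.end()),
    _["fib_eps"] = NumericVector(8 * B.m, 0.0),
    _["fib_xi"] = NumericVector(8 * B.m, 0.0),
    _["fib_dir"] = NumericVector(8 * B.m, 1.0),
    _["fib_sig"] = NumericVector(8 * B.m, 0.0),
    _["tor_en"] = NumericVector(B.m, 0.0),
    _["mem_en"] = NumericVector(std::max(M.k, 0), 0.0),
    _["mem_eps"] = NumericVector(std::max(3 * M.k, 0), 0.0),
    _["time"] = 0.0,
    _["ie"] = 0.0, _["wext"] = 0.0, _["d_damp"] = 0.0, _["d_fric"] = 0.0,
    _["added_mass_fraction"] = m_phys_tot > 0 ? added / m_phys_tot : 0.0,
    _["dt"] = dt);
  return st;
}

// ---------- the phase driver ---------------------------------------------
static Surface make_surface(const List &s, int n) {
  Surface sf;
  std::string kind = as<std::string>(s["kind"]);
  sf.mu = as<double>(s["mu"]);
  sf.k_scale = s.containsElementNamed("k_scale") ? as<double>(s["k_scale"]) : 1.0;
  sf.anchor.assign(3 * n, 0.0);
  sf.active.assign(n, 0);
  sf.hint.assign(n, -1);
  if (kind == "plane") {
    sf.kind = 0;
    NumericVector nn = s["normal"], pf = s["point_from"], pt = s["point_to"];
    for (int c = 0; c < 3; ++c) { sf.n0[c]=nn[c]; sf.p_from[c]=pf[c]; sf.p_to[c]=pt[c]; }
    sf.np = 0;
  } else {
    sf.kind = 1;
    NumericMatrix P = s["centerline"];
    sf.np = P.nrow();
    sf.P.resize(3 * sf.np); sf.S.resize(sf.np); sf.S[0] = 0;
    for (int i = 0; i < sf.np; ++i) {
      for (int c = 0; c < 3; ++c) sf.P[3*i+c] = P(i, c);
      if (i) {
        double d[3] = { P(i,0)-P(i-1,0), P(i,1)-P(i-1,1), P(i,2)-P(i-1,2) };
        sf.S[i] = sf.S[i-1] + vnorm(d);
      }
    }
    sf.morph = s.containsElementNamed("centerline_to") &&
      !Rf_isNull(s["centerline_to"]);
    if (sf.morph) {
      NumericMatrix Pt = s["centerline_to"];
      sf.P_to.resize(3 * sf.np);
      for (int i = 0; i < sf.np; ++i)
        for (int c = 0; c < 3; ++c) sf.P_to[3*i+c] = Pt(i, c);
      sf.P_cur = sf.P;
    }
    sf.R_from = as<double>(s["radius_from"]);
    sf.R_to = as<double>(s["radius_to"]);
    NumericVector wf = s["window_from"], wt = s["window_to"];
    sf.win_from[0]=wf[0]; sf.win_from[1]=wf[1];
    sf.win_to[0]=wt[0]; sf.win_to[1]=wt[1];
  }
  return sf;
}

// [[Rcpp::export]]
List fe_run_phase_cpp(List model, List state, List phase) {
  BeamModel B = unpack_beam(model);
  MemModel M = unpack_mem(model);
  NumericMatrix x = state["x"], v = state["v"], q = state["q"], w = state["w"];
  NumericVector massR = state["mass"], inrR = state["inertia"];
  NumericVector L0R = state["L0"], E0R = state["E0"];
  NumericVector DmInvR = state["DmInv"], ArefR = state["Aref"];
  NumericVector fib_epsR = state["fib_eps"], fib_xiR = state["fib_xi"],
      fib_dirR = state["fib_dir"], fib_sigR = state["fib_sig"];
  NumericVector mem_enR = state["mem_en"], tor_enR = state["tor_en"];
  NumericVector mem_epsR = state["mem_eps"];
  int n = x.nrow();
  std::vector<double> L0(L0R.begin(), L0R.end()), E0(E0R.begin(), E0R.end());
  std::vector<double> DmInv(DmInvR.begin(), DmInvR.end()),
      Aref(ArefR.begin(), ArefR.end());
  std::vector<double> fib_eps(fib_epsR.begin(), fib_epsR.end()),
      fib_xi(fib_xiR.begin(), fib_xiR.end()),
      fib_dir(fib_dirR.begin(), fib_dirR.end()),
      fib_sig(fib_sigR.begin(), fib_sigR.end()),
      mem_en(mem_enR.begin(), mem_enR.end()),
      tor_en(tor_enR.begin(), tor_enR.end()),
      mem_eps(mem_epsR.begin(), mem_epsR.end());
  double visc = model.containsElementNamed("visc") ?
    as<double>(model["visc"]) : 0.0;
  double dt = as<double>(state["dt"]);
  double tme = as<double>(state["time"]);
  double ie = as<double>(state["ie"]), wext = as<double>(state["wext"]);
  double d_damp = as<double>(state["d_damp"]), d_fric = as<double>(state["d_fric"]);

  int n_steps = as<int>(phase["n_steps"]);
  int stride = as<int>(phase["record_stride"]);
  double ramp_frac = as<double>(phase["ramp_frac"]);
  bool stop_on_ke = as<bool>(phase["stop_on_ke"]);
  double ke_tol = as<double>(phase["ke_tol"]);
  NumericVector damp = phase["damping"];   // per node, 1/s
  bool ties_on = as<bool>(phase["ties_active"]);
  bool selfc = as<bool>(phase["self_contact"]);
  bool fatal_on = as<bool>(phase["fatal_check"]);
  double fatal_eps = as<double>(phase["fatal_eps"]);
  double fatal_jmin = as<double>(phase["fatal_jmin"]);
  double fatal_tens = phase.containsElementNamed("fatal_tens") ?
    as<double>(phase["fatal_tens"]) : 1.0;
  // deformation-state criteria must persist over consecutive checks:
  // single-check excursions are dynamic bounce at desk meshes
  int collapse_streak = 0, tens_streak = 0;
  bool rec_fibres = phase.containsElementNamed("record_fibres") &&
    as<bool>(phase["record_fibres"]);

  IntegerMatrix ties;
  int n_tie = 0;
  if (!Rf_isNull(model["ties"])) {
    ties = as<IntegerMatrix>(model["ties"]);
    n_tie = ties.nrow();
  }
  // boundary conditions
  IntegerVector bc_idx;
  NumericMatrix bc_from, bc_to, bc_mask;
  int n_bc = 0;
  if (!Rf_isNull(phase["bc_idx"])) {
    bc_idx = as<IntegerVector>(phase["bc_idx"]);
    bc_from = as<NumericMatrix>(phase["bc_from"]);
    bc_to = as<NumericMatrix>(phase["bc_to"]);
    bc_mask = as<NumericMatrix>(phase["bc_mask"]);
    n_bc = bc_idx.size();
  }
  std::vector<char> rotfix(n, 0);
  if (n_bc && !Rf_isNull(phase["bc_rotfix"])) {
    IntegerVector rf = phase["bc_rotfix"];
    for (int ib = 0; ib < n_bc; ++ib)
      if (rf[ib]) rotfix[bc_idx[ib] - 1] = 1;
  }
  NumericMatrix f_ext;
  bool has_fext = !Rf_isNull(phase["f_ext"]);
  if (has_fext) f_ext = as<NumericMatrix>(phase["f_ext"]);

  List surfL = phase["surfaces"];
  int n_surf = surfL.size();
  std::vector<Surface> surf;
  for (int i = 0; i < n_surf; ++i) surf.push_back(make_surface(surfL[i], n));

  // self-contact neighbor list
  std::vector<std::pair<int,int> > pairs;
  double wire_d = 0.0;
  for (int e = 0; e < B.m; ++e) wire_d = std::max(wire_d, 2.0 * B.r[e]);

  int n_rec_max = n_steps / stride + 2;
  NumericVector rec_t(n_rec_max), rec_ke(n_rec_max), rec_ie(n_rec_max),
      rec_wext(n_rec_max), rec_damp(n_rec_max), rec_fric(n_rec_max),
      rec_econ(n_rec_max), rec_maxeps(n_rec_max),
      rec_mtens(n_rec_max), rec_minJ(n_rec_max);
  NumericMatrix rec_F(n_rec_max, std::max(n_surf, 1)),
      rec_par(n_rec_max, std::max(n_surf, 1));
  NumericMatrix rec_fib;
  if (rec_fibres) rec_fib = NumericMatrix(n_rec_max, 8 * B.m);
  int n_rec = 0;

  std::vector<double> f(3 * n), mom(3 * n), fc(3 * n);
  double ke_peak = 0.0;
  int outcome = 0, steps_done = 0;
  double econ_now = 0.0;
  // surface forces averaged between records (smooths dynamic ringing)
  std::vector<double> surfF_acc(std::max(n_surf, 1), 0.0);
  int acc_count = 0;

  for (int step = 0; step < n_steps; ++step) {
    double tau = (ramp_frac > 0) ? std::min(1.0, (step + 1.0) / (ramp_frac * n_steps)) : 1.0;
    double sramp = 0.5 - 0.5 * std::cos(M_PI * tau);
    std::fill(f.begin(), f.end(), 0.0);
    std::fill(mom.begin(), mom.end(), 0.0);
    std::fill(fc.begin(), fc.end(), 0.0);
    double max_eps = 0.0, minJ = 1e300, max_tens = -1e300;
    double ie_inc = 0.0;
    beam_forces(B, L0, E0, x, q, fib_eps, fib_xi, fib_dir, fib_sig, tor_en,
                true, f.data(), mom.data(), &ie_inc, &max_eps, visc, &d_damp);
    if (M.k)
      mem_forces(M, DmInv, Aref, x, f.data(), &ie_inc, mem_en, mem_eps,
                 &minJ, &max_tens, visc, &d_damp);
    ie += ie_inc;

    // contact
    econ_now = 0.0;
    std::vector<double> surfF(n_surf, 0.0), surfPar(n_surf, 0.0);
    for (int si = 0; si < n_surf; ++si) {
      Surface &sf = surf[si];
      double fricW = 0.0;
      if (sf.kind == 0) {
        double pp[3];
        for (int c = 0; c < 3; ++c)
          pp[c] = sf.p_from[c] + sramp * (sf.p_to[c] - sf.p_from[c]);
        surfPar[si] = 2.0 * std::sqrt(pp[0]*pp[0] + pp[1]*pp[1]); // crimper dia
        for (int i = 0; i < n; ++i) {
          double d = (x(i,0)-pp[0])*sf.n0[0] + (x(i,1)-pp[1])*sf.n0[1] + (x(i,2)-pp[2])*sf.n0[2];
          if (d < 0) {
            double kp = 0.1 * massR[i] / (dt * dt) * sf.k_scale;
            double fn = -kp * d;
            surfF[si] += fn;
            econ_now += 0.5 * kp * d * d;
            for (int c = 0; c < 3; ++c) fc[3*i+c] += fn * sf.n0[c];
            // friction
            if (sf.mu > 0) {
              double xt[3] = { x(i,0), x(i,1), x(i,2) };
              vaxpy(xt, -d, sf.n0);  // projected point on plane
              if (!sf.active[i]) { vcopy(&sf.anchor[3*i], xt); sf.active[i] = 1; }
              double ft[3] = { sf.anchor[3*i]-xt[0], sf.anchor[3*i+1]-xt[1], sf.anchor[3*i+2]-xt[2] };
              double ftn = vdot(ft, sf.n0); vaxpy(ft, -ftn, sf.n0);
              double ftmag = vnorm(ft) * kp;
              double fmax = sf.mu * fn;
              if (ftmag > fmax && ftmag > 1e-30) {
                double sc = fmax / ftmag;
                // move anchor toward current point (slip), dissipate
                double slip[3] = { (1.0 - sc) * ft[0], (1.0 - sc) * ft[1], (1.0 - sc) * ft[2] };
                fricW += fmax * vnorm(slip);
                for (int c = 0; c < 3; ++c) sf.anchor[3*i+c] -= slip[c];
                vscale(ft, sc);
              }
              for (int c = 0; c < 3; ++c) fc[3*i+c] += ft[c] * kp;
              econ_now += 0.5 * kp * vdot(ft, ft);
            }
          } else if (sf.active[i]) sf.active[i] = 0;
        }
      } else {
        double R = sf.R_from + sramp * (sf.R_to - sf.R_from);
        double w0 = sf.win_from[0] + sramp * (sf.win_to[0] - sf.win_from[0]);
        double w1 = sf.win_from[1] + sramp * (sf.win_to[1] - sf.win_from[1]);
        surfPar[si] = R;
        if (sf.morph) {
          // morph the centerline and refresh cumulative arc length
          for (int i = 0; i < 3 * sf.np; ++i)
            sf.P_cur[i] = sf.P[i] + sramp * (sf.P_to[i] - sf.P[i]);
          std::swap(sf.P, sf.P_cur);
          sf.S[0] = 0;
          for (int i = 1; i < sf.np; ++i) {
            double d[3] = { sf.P[3*i]-sf.P[3*(i-1)], sf.P[3*i+1]-sf.P[3*(i-1)+1],
                            sf.P[3*i+2]-sf.P[3*(i-1)+2] };
            sf.S[i] = sf.S[i-1] + vnorm(d);
          }
        }
        for (int i = 0; i < n; ++i) {
          double xx[3] = { x(i,0), x(i,1), x(i,2) }, s, cpt[3], tg[3];
          int hh = (step % 50 == 0) ? -1 : sf.hint[i];
          polyline_closest(sf, xx, s, cpt, tg, &hh);
          sf.hint[i] = hh;
          if (s < w0 || s > w1) { sf.active[i] = 0; continue; }
          double rho[3] = { xx[0]-cpt[0], xx[1]-cpt[1], xx[2]-cpt[2] };
          double rn = vdot(rho, tg);
          vaxpy(rho, -rn, tg);
          double r = vnorm(rho);
          if (r > R && r > 1e-12) {
            double kp = 0.1 * massR[i] / (dt * dt) * sf.k_scale;
            double g = r - R;
            double fn = kp * g;
            surfF[si] += fn;
            econ_now += 0.5 * kp * g * g;
            double nr[3] = { rho[0]/r, rho[1]/r, rho[2]/r };
            for (int c = 0; c < 3; ++c) fc[3*i+c] -= fn * nr[c];
            if (sf.mu > 0) {
              double xt[3]; vcopy(xt, xx); vaxpy(xt, -g, nr);
              if (!sf.active[i]) { vcopy(&sf.anchor[3*i], xt); sf.active[i] = 1; }
              double ft[3] = { sf.anchor[3*i]-xt[0], sf.anchor[3*i+1]-xt[1], sf.anchor[3*i+2]-xt[2] };
              double ftn = vdot(ft, nr); vaxpy(ft, -ftn, nr);
              double ftmag = vnorm(ft) * kp;
              double fmax = sf.mu * fn;
              if (ftmag > fmax && ftmag > 1e-30) {
                double sc = fmax / ftmag;
                double slip[3] = { (1.0 - sc) * ft[0], (1.0 - sc) * ft[1], (1.0 - sc) * ft[2] };
                fricW += fmax * vnorm(slip);
                for (int c = 0; c < 3; ++c) sf.anchor[3*i+c] -= slip[c];
                vscale(ft, sc);
              }
              for (int c = 0; c < 3; ++c) fc[3*i+c] += ft[c] * kp;
              econ_now += 0.5 * kp * vdot(ft, ft);
            }
          } else if (sf.active[i]) sf.active[i] = 0;
        }
        if (sf.kind == 1 && sf.morph) std::swap(sf.P, sf.P_cur);
      }
      d_fric += fricW;
    }

    // beam self-contact
    if (selfc && B.m > 1) {
      if (step % 25 == 0) {
        pairs.clear();
        // candidates: segment pairs close enough to touch within the
        // rebuild horizon (node-distance proxy, half-millimetre margin)
        double cut = wire_d + 1.5;
        for (int e = 0; e < B.m; ++e) {
          for (int e2 = e + 1; e2 < B.m; ++e2) {
            int sep = std::min(std::abs(e2 - e), B.m - std::abs(e2 - e));
            if (sep <= 2) continue;
            double dx = x(B.na[e],0) - x(B.na[e2],0);
            double dy = x(B.na[e],1) - x(B.na[e2],1);
            double dz = x(B.na[e],2) - x(B.na[e2],2);
            if (dx*dx + dy*dy + dz*dz < cut * cut) pairs.push_back(std::make_pair(e, e2));
          }
        }
      }
      for (size_t pi = 0; pi < pairs.size(); ++pi) {
        int e = pairs[pi].first, e2 = pairs[pi].second;
        double p1[3] = { x(B.na[e],0), x(B.na[e],1), x(B.na[e],2) };
        double q1[3] = { x(B.nb[e],0), x(B.nb[e],1), x(B.nb[e],2) };
        double p2[3] = { x(B.na[e2],0), x(B.na[e2],1), x(B.na[e2],2) };
        double q2[3] = { x(B.nb[e2],0), x(B.nb[e2],1), x(B.nb[e2],2) };
        double s, t;
        double d = seg_seg_dist(p1, q1, p2, q2, s, t);
        double dmin = B.r[e] + B.r[e2];
        if (d < dmin && d > 1e-12) {
          double c1[3] = { p1[0]+s*(q1[0]-p1[0]), p1[1]+s*(q1[1]-p1[1]), p1[2]+s*(q1[2]-p1[2]) };
          double c3[3] = { p2[0]+t*(q2[0]-p2[0]), p2[1]+t*(q2[1]-p2[1]), p2[2]+t*(q2[2]-p2[2]) };
          double nr[3] = { c1[0]-c3[0], c1[1]-c3[1], c1[2]-c3[2] };
          vscale(nr, 1.0 / d);
          double kp = 0.05 * std::min(massR[B.na[e]], massR[B.na[e2]]) / (dt * dt);
          double fn = kp * (dmin - d);
          econ_now += 0.5 * kp * (dmin - d) * (dmin - d);
          for (int c = 0; c < 3; ++c) {
            fc[3*B.na[e]+c]  += fn * nr[c] * (1 - s);
            fc[3*B.nb[e]+c]  += fn * nr[c] * s;
            fc[3*B.na[e2]+c] -= fn * nr[c] * (1 - t);
            fc[3*B.nb[e2]+c] -= fn * nr[c] * t;
          }
        }
      }
    }

    if (has_fext)
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c) f[3*i+c] += f_ext(i, c);

    // integrate translations; work and dissipation use the midpoint
    // velocity, consistent with the central-difference energy identity
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      double mi = massR[i], di = damp[i];
      for (int c = 0; c < 3; ++c) {
        double vold = v(i, c);
        double vnew = vold * (1.0 - di * dt) + dt * (f[3*i+c] + fc[3*i+c]) / mi;
        v(i, c) = vnew;
        double vbar = 0.5 * (vold + vnew);
        d_damp += di * mi * vold * vbar * dt;
        wext += fc[3*i+c] * vbar * dt;
        if (has_fext) wext += f_ext(i, c) * vbar * dt;
      }
    }
    // ties: merged translational dofs; averaging the momenta after the
    // velocity update is the exact update of the merged node (forces,
    // damping and masses of both sides combine consistently)
    if (ties_on && n_tie) {
      for (int tpair = 0; tpair < n_tie; ++tpair) {
        int a = ties(tpair, 0) - 1, bnd = ties(tpair, 1) - 1;
        double msum = massR[a] + massR[bnd];
        for (int c = 0; c < 3; ++c) {
          double vc = (massR[a] * v(a,c) + massR[bnd] * v(bnd,c)) / msum;
          v(a, c) = vc; v(bnd, c) = vc;
          double xm = 0.5 * (x(a, c) + x(bnd, c));
          x(a, c) = xm; x(bnd, c) = xm;
        }
      }
    }
    // prescribed motion (overrides)
    if (n_bc) {
      for (int ib = 0; ib < n_bc; ++ib) {
        int i = bc_idx[ib] - 1;
        for (int c = 0; c < 3; ++c) {
          if (bc_mask(ib, c) == 0) continue;
          double xt = bc_from(ib, c) + sramp * (bc_to(ib, c) - bc_from(ib, c));
          double vreq = (xt - x(i, c)) / dt;
          // constraint reaction work: r = m (vreq - vfree)/dt acting through vreq dt
          double r = massR[i] * (vreq - v(i, c)) / dt;
          wext += r * vreq * dt;
          v(i, c) = vreq;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      double mi = massR[i];
      for (int c = 0; c < 3; ++c) {
        x(i, c) += dt * v(i, c);
        ke += 0.5 * mi * v(i, c) * v(i, c);
      }
    }

    // rotations
    for (int i = 0; i < n; ++i) {
      double Ii = inrR[i];
      if (Ii <= 0) continue;
      if (rotfix[i]) { w(i,0) = w(i,1) = w(i,2) = 0; continue; }
      double di = damp[i];
      double wv[3];
      for (int c = 0; c < 3; ++c) {
        double wold = w(i, c);
        double wnew = wold * (1.0 - di * dt) + dt * mom[3*i+c] / Ii;
        w(i, c) = wnew;
        wv[c] = wnew;
        ke += 0.5 * Ii * wnew * wnew;
        d_damp += di * Ii * 0.25 * (wold + wnew) * (wold + wnew) * dt;
      }
      double qi[4] = { q(i,0), q(i,1), q(i,2), q(i,3) };
      quat_rotate(qi, wv, dt);
      q(i,0) = qi[0]; q(i,1) = qi[1]; q(i,2) = qi[2]; q(i,3) = qi[3];
    }
    // BC nodes: freeze rotation as well when fully clamped
    tme += dt;
    ++steps_done;
    if (ke > ke_peak) ke_peak = ke;

    // records
    for (int si = 0; si < n_surf; ++si) surfF_acc[si] += surfF[si];
    ++acc_count;
    if (step % stride == 0 || step == n_steps - 1) {
      rec_t[n_rec] = tme; rec_ke[n_rec] = ke; rec_ie[n_rec] = ie;
      rec_wext[n_rec] = wext; rec_damp[n_rec] = d_damp; rec_fric[n_rec] = d_fric;
      rec_econ[n_rec] = econ_now; rec_maxeps[n_rec] = max_eps;
      rec_mtens[n_rec] = max_tens; rec_minJ[n_rec] = minJ;
      for (int si = 0; si < n_surf; ++si) {
        rec_F(n_rec, si) = surfF_acc[si] / acc_count;
        rec_par(n_rec, si) = surfPar[si];
        surfF_acc[si] = 0.0;
      }
      acc_count = 0;
      if (rec_fibres)
        for (int ii = 0; ii < 8 * B.m; ++ii) rec_fib(n_rec, ii) = fib_eps[ii];
      ++n_rec;
    }
    // fatal / divergence checks
    if (step % 20 == 0 || step == n_steps - 1) {
      if (!std::isfinite(ke) || !std::isfinite(ie) || ke > 1e12) { outcome = 2; break; }
      if (fatal_on) {
        // bad-deformation stop: overstrained wire fibres; membrane
        // elements stretched beyond destruction; or stress-bearing
        // membrane elements persistently collapsed (transient dips are
        // dynamic bounce; fabric wrinkling collapse is stress-free and
        // intended, hence exempt)
        int bad = 0;
        if (max_eps > fatal_eps) bad = 1;              // wire fibre
        if (M.k && max_tens > fatal_tens) ++tens_streak;
        else tens_streak = 0;
        if (tens_streak >= 3) bad = 3;                 // membrane destroyed
        if (M.k && M.cfac > 0 && minJ < fatal_jmin) ++collapse_streak;
        else collapse_streak = 0;
        if (collapse_streak >= 3) bad = 4;             // persistent collapse
        if (bad) { outcome = bad; break; }
      }
    }
    if (stop_on_ke && tau >= 1.0 && ke_peak > 0 && ke < ke_tol * ke_peak) {
      // record the terminal step so callers see the converged energies
      rec_t[n_rec] = tme; rec_ke[n_rec] = ke; rec_ie[n_rec] = ie;
      rec_wext[n_rec] = wext; rec_damp[n_rec] = d_damp; rec_fric[n_rec] = d_fric;
      rec_econ[n_rec] = econ_now; rec_maxeps[n_rec] = 0.0;
      rec_mtens[n_rec] = 0.0; rec_minJ[n_rec] = 1.0;
      for (int si = 0; si < n_surf; ++si) {
        rec_F(n_rec, si) = acc_count ? surfF_acc[si] / acc_count : 0.0;
        rec_par(n_rec, si) = surfPar[si];
      }
      ++n_rec;
      break;
    }
  }

  // write back state
  state["time"] = tme; state["ie"] = ie; state["wext"] = wext;
  state["d_damp"] = d_damp; state["d_fric"] = d_fric;
  std::copy(fib_eps.begin(), fib_eps.end(), fib_epsR.begin());
  std::copy(fib_xi.begin(), fib_xi.end(), fib_xiR.begin());
  std::copy(fib_dir.begin(), fib_dir.end(), fib_dirR.begin());
  std::copy(fib_sig.begin(), fib_sig.end(), fib_sigR.begin());
  std::copy(mem_en.begin(), mem_en.end(), mem_enR.begin());
  std::copy(tor_en.begin(), tor_en.end(), tor_enR.begin());
  std::copy(mem_eps.begin(), mem_eps.end(), mem_epsR.begin());

  List rec = List::create(
    _["time"] = NumericVector(rec_t.begin(), rec_t.begin() + n_rec),
    _["ke"] = NumericVector(rec_ke.begin(), rec_ke.begin() + n_rec),
    _["ie"] = NumericVector(rec_ie.begin(), rec_ie.begin() + n_rec),
    _["wext"] = NumericVector(rec_wext.begin(), rec_wext.begin() + n_rec),
    _["d_damp"] = NumericVector(rec_damp.begin(), rec_damp.begin() + n_rec),
    _["d_fric"] = NumericVector(rec_fric.begin(), rec_fric.begin() + n_rec),
    _["e_contact"] = NumericVector(rec_econ.begin(), rec_econ.begin() + n_rec),
    _["max_fib_eps"] = NumericVector(rec_maxeps.begin(), rec_maxeps.begin() + n_rec),
    _["max_mem_tens"] = NumericVector(rec_mtens.begin(), rec_mtens.begin() + n_rec),
    _["min_mem_J"] = NumericVector(rec_minJ.begin(), rec_minJ.begin() + n_rec),
    _["surf_force"] = rec_F(Range(0, std::max(n_rec - 1, 0)), _),
    _["surf_param"] = rec_par(Range(0, std::max(n_rec - 1, 0)), _),
    _["fib_eps"] = R_NilValue);
  if (rec_fibres)
    rec["fib_eps"] = rec_fib(Range(0, std::max(n_rec - 1, 0)), _);
  return List::create(_["state"] = state, _["records"] = rec,
                      _["outcome"] = outcome, _["steps_done"] = steps_done,
                      _["ke_peak"] = ke_peak);
}
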