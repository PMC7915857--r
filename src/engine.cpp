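// Core compiled routines: potentials/forces for the twistable bead-spring
// fiber + cohesin ring, the overdamped Langevin integrator with motor,
// moving nicks and per-bead drag, and Gauss-integral topology kernels.
#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// ---------------------------------------------------------------- vec3 utils

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

static inline double wrap_angle(double x) {
  // to (-pi, pi]
  double w = std::remainder(x, TWO_PI);
  if (w <= -M_PI) w += TWO_PI;
  return w;
}

// 3 x n coordinate block stored column-major (x,y,z contiguous per particle)
struct Coords {
  std::vector<double> x;
  int n;
  Coords() : n(0) {}
  explicit Coords(int n_) : x(3 * n_, 0.0), n(n_) {}
  double* p(int i) { return &x[3 * i]; }
  const double* p(int i) const { return &x[3 * i]; }
};

static Coords from_matrix(const NumericMatrix& m) {
  Coords c(m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    for (int k = 0; k < 3; ++k) c.x[3 * i + k] = m(i, k);
  return c;
}
static NumericMatrix to_matrix(const Coords& c) {
  NumericMatrix m(c.n, 3);
  for (int i = 0; i < c.n; ++i)
    for (int k = 0; k < 3; ++k) m(i, k) = c.x[3 * i + k];
  return m;
}

// ------------------------------------------------------------------- params

struct SysParams {
  // fiber
  double bond_k, bond_r0, wca_eps, sigma, bend_Kb, tors_C, r_p, gamma_R;
  double tether_k, perp_k;
  // ring
  double ring_bond_k, ring_bond_r0, ring_Kb, ring_excl_sigma;
  int loading_bead;     // 0-based; -1 if none
  bool closed;
  int tors_form;        // 1 = cosine (default), 0 = harmonic
  // integration
  double dt, kT;
  double force_cap;     // <= 0: no cap
};

static SysParams parse_params(const List& p) {
  SysParams s;
  s.bond_k = as<double>(p["bond_k"]);
  s.bond_r0 = as<double>(p["bond_r0"]);
  s.wca_eps = as<double>(p["wca_epsilon"]);
  s.sigma = as<double>(p["bead_size"]);
  s.bend_Kb = as<double>(p["bend_Kb"]);
  s.tors_C = as<double>(p["torsion_C"]);
  s.r_p = as<double>(p["periaxial_offset"]);
  s.gamma_R = as<double>(p["gamma_R"]);
  s.tether_k = p.containsElementNamed("tether_k") ? as<double>(p["tether_k"]) : 600.0;
  s.perp_k = p.containsElementNamed("perp_k") ? as<double>(p["perp_k"]) : 100.0;
  s.ring_bond_k = p.containsElementNamed("ring_bond_k") ? as<double>(p["ring_bond_k"]) : 100.0;
  s.ring_bond_r0 = p.containsElementNamed("ring_bond_r0") ? as<double>(p["ring_bond_r0"]) : 1.0;
  s.ring_Kb = p.containsElementNamed("ring_Kb") ? as<double>(p["ring_Kb"]) : 20.0;
  s.ring_excl_sigma = p.containsElementNamed("ring_excl_sigma") ? as<double>(p["ring_excl_sigma"]) : 3.0;
  s.loading_bead = p.containsElementNamed("loading_bead") ? as<int>(p["loading_bead"]) : -1;
  s.tors_form = 1;
  if (p.containsElementNamed("torsion_form")) {
    std::string tf = as<std::string>(p["torsion_form"]);
    s.tors_form = (tf == "harmonic") ? 0 : 1;
  }
  s.closed = p.containsElementNamed("closed") ? as<bool>(p["closed"]) : true;
  s.dt = p.containsElementNamed("dt") ? as<double>(p["dt"]) : 0.0025;
  s.kT = p.containsElementNamed("kT") ? as<double>(p["kT"]) : 1.0;
  s.force_cap = p.containsElementNamed("force_cap") ? as<double>(p["force_cap"]) : -1.0;
  return s;
}

// ------------------------------------------------------------------- forces

// harmonic bond between particles a,b of one coordinate block
static inline double bond_term(Coords& f, const Coords& r, int a, int b,
                               double k, double r0) {
  double d[3];
  for (int q = 0; q < 3; ++q) d[q] = r.p(b)[q] - r.p(a)[q];
  double len = norm3(d);
  if (len < 1e-12) return 0.0;
  double dev = len - r0;
  double coef = k * dev / len;  // dE/dlen * unit vector
  double* fa = f.p(a);
  double* fb = f.p(b);
  for (int q = 0; q < 3; ++q) {
    fa[q] += coef * d[q];
    fb[q] -= coef * d[q];
  }
  return 0.5 * k * dev * dev;
}

// WCA (truncated-shifted LJ, purely repulsive) between a in block ra, b in rb
static inline double wca_term(Coords& fa_blk, Coords& fb_blk, const Coords& ra,
                              const Coords& rb, int a, int b, double eps,
                              double sig) {
  double d[3];
  for (int q = 0; q < 3; ++q) d[q] = rb.p(b)[q] - ra.p(a)[q];
  double r2 = dot3(d, d);
  double rc2 = sig * sig * std::pow(2.0, 1.0 / 3.0);
  if (r2 >= rc2) return 0.0;
  if (r2 < 1e-12) r2 = 1e-12;
  double sr2 = sig * sig / r2;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double e = 4.0 * eps * (sr12 - sr6) + eps;
  // F = -dE/dr ; dE/dr2 = 4 eps (-12 sr12 + 6 sr6)/ (2 r2)... use standard:
  double coef = 24.0 * eps * (2.0 * sr12 - sr6) / r2;  // magnitude along -d
  double* fa = fa_blk.p(a);
  double* fb = fb_blk.p(b);
  for (int q = 0; q < 3; ++q) {
    fa[q] -= coef * d[q];
    fb[q] += coef * d[q];
  }
  return e;
}

// bending K(1 - cos theta) at middle bead j between i and k
static inline double bend_term(Coords& f, const Coords& r, int i, int j, int k,
                               double K) {
  double b1[3], b2[3];
  for (int q = 0; q < 3; ++q) {
    b1[q] = r.p(j)[q] - r.p(i)[q];
    b2[q] = r.p(k)[q] - r.p(j)[q];
  }
  double l1 = norm3(b1), l2 = norm3(b2);
  if (l1 < 1e-12 || l2 < 1e-12) return 0.0;
  double u[3], v[3];
  for (int q = 0; q < 3; ++q) {
    u[q] = b1[q] / l1;
    v[q] = b2[q] / l2;
  }
  double c = dot3(u, v);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  // dcos/db1 = (v - c u)/l1 ; dcos/db2 = (u - c v)/l2
  double g1[3], g2[3];
  for (int q = 0; q < 3; ++q) {
    g1[q] = (v[q] - c * u[q]) / l1;
    g2[q] = (u[q] - c * v[q]) / l2;
  }
  // E = K (1 - c); F_x = -dE/dx = K dcos/dx
  double* fi = f.p(i);
  double* fj = f.p(j);
  double* fk = f.p(k);
  for (int q = 0; q < 3; ++q) {
    fi[q] += K * (-g1[q]);
    fj[q] += K * (g1[q] - g2[q]);
    fk[q] += K * (g2[q]);
  }
  return K * (1.0 - c);
}

// Twist angle of bond (i -> j): signed rotation from periaxial offset u_i to
// u_j about the bond direction, in (-pi, pi]. Computed as the dihedral of
// (pax_i, pos_i, pos_j, pax_j) in the convention that parallel offsets give 0.
static double twist_angle_pair(const double* pi_, const double* ri,
                               const double* rj, const double* pj,
                               bool* degenerate) {
  double b1[3], b2[3], b3[3];
  for (int q = 0; q < 3; ++q) {
    b1[q] = ri[q] - pi_[q];  // -u_i
    b2[q] = rj[q] - ri[q];
    b3[q] = pj[q] - rj[q];   // u_j
  }
  double m[3], nn[3];
  cross3(b1, b2, m);
  cross3(b2, b3, nn);
  double m2 = dot3(m, m), n2 = dot3(nn, nn);
  if (degenerate) *degenerate = (m2 < 1e-14 || n2 < 1e-14);
  if (m2 < 1e-14 || n2 < 1e-14) return 0.0;
  double mxn[3];
  cross3(m, nn, mxn);
  double y = dot3(b2, mxn) / norm3(b2);
  double x = dot3(m, nn);
  return std::atan2(y, x);
}

// torsional force for active bond (i->j): E = C/2 * wrap(phi - phi0)^2
// adds forces on pax_i, pos_i, pos_j, pax_j
static double torsion_term(Coords& f_pos, Coords& f_pax, const Coords& pos,
                           const Coords& pax, int i, int j, double C,
                           double phi0, int tors_form) {
  double b1[3], b2[3], b3[3];
  const double* P1 = pax.p(i);
  const double* P2 = pos.p(i);
  const double* P3 = pos.p(j);
  const double* P4 = pax.p(j);
  for (int q = 0; q < 3; ++q) {
    b1[q] = P2[q] - P1[q];
    b2[q] = P3[q] - P2[q];
    b3[q] = P4[q] - P3[q];
  }
  double m[3], nn[3];
  cross3(b1, b2, m);
  cross3(b2, b3, nn);
  double m2 = dot3(m, m), n2 = dot3(nn, nn);
  if (m2 < 1e-14 || n2 < 1e-14) return 0.0;  // degenerate: no force
  double lb2 = norm3(b2);
  double mxn[3];
  cross3(m, nn, mxn);
  double phi = std::atan2(dot3(b2, mxn) / lb2, dot3(m, nn));
  double dphi = wrap_angle(phi - phi0);
  // bounded cosine form C (1 - cos dphi): harmonic to second order with
  // spring constant C, continuous torque across the wrap point
  bool cosine = (tors_form == 1);
  double e = cosine ? C * (1.0 - std::cos(dphi)) : 0.5 * C * dphi * dphi;
  // near-degenerate lever arms (offset almost parallel to the bond, e.g.
  // at a rare sharp kink) make the angle gradient singular; keep the
  // energy but drop the force there
  if (m2 < 2.5e-3 || n2 < 2.5e-3) return e;
  // gradient of phi wrt the four points (Blondel-Karplus form)
  double d1[3], d4[3];
  for (int q = 0; q < 3; ++q) {
    d1[q] = -(lb2 / m2) * m[q];
    d4[q] = (lb2 / n2) * nn[q];
  }
  double s12 = dot3(b1, b2) / (lb2 * lb2);
  double s32 = dot3(b3, b2) / (lb2 * lb2);
  double d2[3], d3[3];
  for (int q = 0; q < 3; ++q) {
    d2[q] = -(1.0 + s12) * d1[q] + s32 * d4[q];
    d3[q] = -(1.0 + s32) * d4[q] + s12 * d1[q];
  }
  double g = cosine ? -C * std::sin(dphi) : -C * dphi;  // -dE/dphi
  double* F1 = f_pax.p(i);
  double* F2 = f_pos.p(i);
  double* F3 = f_pos.p(j);
  double* F4 = f_pax.p(j);
  // bound each per-term contribution: the lever factors diverge as the
  // geometry degenerates
  const double tcap = 60.0;
  double* dd[4] = {d1, d2, d3, d4};
  for (int k = 0; k < 4; ++k) {
    double l = std::fabs(g) * norm3(dd[k]);
    if (l > tcap) {
      double s = tcap / l;
      for (int q = 0; q < 3; ++q) dd[k][q] *= s;
    }
  }
  for (int q = 0; q < 3; ++q) {
    F1[q] += g * d1[q];
    F2[q] += g * d2[q];
    F3[q] += g * d3[q];
    F4[q] += g * d4[q];
  }
  return e;
}

// full force/energy evaluation for fiber (+ optional ring)
// torsion_active / phi0 have length n_bonds (n if closed, n-1 if open)
static double all_forces(const Coords& pos, const Coords& pax,
                         const Coords& ring, const std::vector<int>& tors_act,
                         const std::vector<double>& phi0, const SysParams& sp,
                         Coords& f_pos, Coords& f_pax, Coords& f_ring) {
  int n = pos.n;
  int m = ring.n;
  std::fill(f_pos.x.begin(), f_pos.x.end(), 0.0);
  std::fill(f_pax.x.begin(), f_pax.x.end(), 0.0);
  std::fill(f_ring.x.begin(), f_ring.x.end(), 0.0);
  double E = 0.0;
  int nb = sp.closed ? n : n - 1;
  // bonds
  for (int i = 0; i < nb; ++i)
    E += bond_term(f_pos, pos, i, (i + 1) % n, sp.bond_k, sp.bond_r0);
  // bending
  if (sp.bend_Kb > 0) {
    int i0 = sp.closed ? 0 : 1;
    int i1 = sp.closed ? n : n - 1;
    for (int j = i0; j < i1; ++j)
      E += bend_term(f_pos, pos, (j - 1 + n) % n, j, (j + 1) % n, sp.bend_Kb);
  }
  // excluded volume fiber-fiber (skip bonded neighbours)
  if (sp.wca_eps > 0) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 2; j < n; ++j) {
        if (sp.closed && i == 0 && j == n - 1) continue;  // bonded closure
        E += wca_term(f_pos, f_pos, pos, pos, i, j, sp.wca_eps, sp.sigma);
      }
    }
  }
  // periaxial attachment: stiff radial tether |u| ~ r_p plus a
  // perpendicularity penalty on the component of the offset along the
  // local (chord) tangent; together they keep the frame bead on a ring
  // of radius r_p about the backbone axis while leaving the azimuthal
  // angle - the twist degree of freedom - free
  if (sp.tether_k > 0) {
    for (int i = 0; i < n; ++i) {
      double u[3];
      for (int q = 0; q < 3; ++q) u[q] = pax.p(i)[q] - pos.p(i)[q];
      double lu = norm3(u);
      if (lu < 1e-12) continue;
      double dev = lu - sp.r_p;
      double coef = sp.tether_k * dev / lu;
      for (int q = 0; q < 3; ++q) {
        f_pax.p(i)[q] -= coef * u[q];
        f_pos.p(i)[q] += coef * u[q];
      }
      E += 0.5 * sp.tether_k * dev * dev;
      // chord tangent
      int ip = sp.closed ? (i + 1) % n : (i + 1 < n ? i + 1 : i);
      int im = sp.closed ? (i - 1 + n) % n : (i - 1 >= 0 ? i - 1 : i);
      double w[3];
      for (int q = 0; q < 3; ++q) w[q] = pos.p(ip)[q] - pos.p(im)[q];
      double lw = norm3(w);
      if (lw < 1e-12) continue;
      double mhat[3];
      for (int q = 0; q < 3; ++q) mhat[q] = w[q] / lw;
      double sproj = dot3(u, mhat);
      E += 0.5 * sp.perp_k * sproj * sproj;
      double g = -sp.perp_k * sproj;
      // ds/dpax = mhat ; ds/dpos_i = -mhat ; ds/dw = (u - s mhat)/|w|
      double dw[3];
      for (int q = 0; q < 3; ++q) dw[q] = (u[q] - sproj * mhat[q]) / lw;
      for (int q = 0; q < 3; ++q) {
        f_pax.p(i)[q] += g * mhat[q];
        f_pos.p(i)[q] -= g * mhat[q];
        f_pos.p(ip)[q] += g * dw[q];
        f_pos.p(im)[q] -= g * dw[q];
      }
    }
  }
  // torsion
  if (sp.tors_C > 0) {
    for (int i = 0; i < nb; ++i) {
      if (!tors_act[i]) continue;
      E += torsion_term(f_pos, f_pax, pos, pax, i, (i + 1) % n, sp.tors_C,
                        phi0[i], sp.tors_form);
    }
  }
  // ring
  if (m > 0) {
    for (int i = 0; i < m; ++i)
      E += bond_term(f_ring, ring, i, (i + 1) % m, sp.ring_bond_k,
                     sp.ring_bond_r0);
    if (sp.ring_Kb > 0)
      for (int j = 0; j < m; ++j)
        E += bend_term(f_ring, ring, (j - 1 + m) % m, j, (j + 1) % m,
                       sp.ring_Kb);
    if (sp.wca_eps > 0) {
      for (int i = 0; i < m; ++i)
        for (int j = i + 2; j < m; ++j) {
          if (i == 0 && j == m - 1) continue;
          E += wca_term(f_ring, f_ring, ring, ring, i, j, sp.wca_eps,
                        sp.sigma);
        }
      for (int i = 0; i < n; ++i) {
        double sig = (i == sp.loading_bead) ? sp.ring_excl_sigma : sp.sigma;
        for (int j = 0; j < m; ++j)
          E += wca_term(f_pos, f_ring, pos, ring, i, j, sp.wca_eps, sig);
      }
    }
  }
  return E;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix pax, NumericMatrix ring,
                IntegerVector torsion_active, NumericVector phi0,
                List params) {
  SysParams sp = parse_params(params);
  Coords P = from_matrix(pos), X = from_matrix(pax), R = from_matrix(ring);
  std::vector<int> ta(torsion_active.begin(), torsion_active.end());
  std::vector<double> p0(phi0.begin(), phi0.end());
  Coords fp(P.n), fx(X.n), fr(R.n);
  double E = all_forces(P, X, R, ta, p0, sp, fp, fx, fr);
  return List::create(_["energy"] = E, _["f_pos"] = to_matrix(fp),
                      _["f_pax"] = to_matrix(fx), _["f_ring"] = to_matrix(fr));
}

// [[Rcpp::export]]
NumericVector cpp_twist_angles(NumericMatrix pos, NumericMatrix pax,
                               bool closed) {
  int n = pos.nrow();
  int nb = closed ? n : n - 1;
  NumericVector out(nb);
  Coords P = from_matrix(pos), X = from_matrix(pax);
  for (int i = 0; i < nb; ++i) {
    int j = (i + 1) % n;
    bool deg = false;
    out[i] = twist_angle_pair(X.p(i), P.p(i), P.p(j), X.p(j), &deg);
    if (deg) out[i] = NA_REAL;
  }
  return out;
}

// ------------------------------------------------- topology: writhe / link

// exact Gauss integral for a pair of straight segments (Klenin & Langowski)
static double segment_pair_omega(const double* p1, const double* p2,
                                 const double* p3, const double* p4) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  for (int q = 0; q < 3; ++q) {
    r12[q] = p2[q] - p1[q];
    r34[q] = p4[q] - p3[q];
    r13[q] = p3[q] - p1[q];
    r14[q] = p4[q] - p1[q];
    r23[q] = p3[q] - p2[q];
    r24[q] = p4[q] - p2[q];
  }
  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1);
  cross3(r14, r24, n2);
  cross3(r24, r23, n3);
  cross3(r23, r13, n4);
  double l1 = norm3(n1), l2 = norm3(n2), l3 = norm3(n3), l4 = norm3(n4);
  if (l1 < 1e-12 || l2 < 1e-12 || l3 < 1e-12 || l4 < 1e-12) return 0.0;
  for (int q = 0; q < 3; ++q) {
    n1[q] /= l1;
    n2[q] /= l2;
    n3[q] /= l3;
    n4[q] /= l4;
  }
  auto casin = [](double v) {
    if (v > 1.0) v = 1.0;
    if (v < -1.0) v = -1.0;
    return std::asin(v);
  };
  double omega = casin(dot3(n1, n2)) + casin(dot3(n2, n3)) +
                 casin(dot3(n3, n4)) + casin(dot3(n4, n1));
  double cr[3];
  cross3(r34, r12, cr);
  double s = dot3(cr, r13);
  double sign = (s > 0) - (s < 0);
  return omega * sign;
}

// [[Rcpp::export]]
double cpp_writhe(NumericMatrix pts, bool closed) {
  int n = pts.nrow();
  Coords P = from_matrix(pts);
  int nseg = closed ? n : n - 1;
  double wr = 0.0;
  for (int i = 0; i < nseg; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < nseg; ++j) {
      if (closed && i == 0 && j == nseg - 1) continue;  // adjacent via closure
      int j2 = (j + 1) % n;
      wr += segment_pair_omega(P.p(i), P.p(i2), P.p(j), P.p(j2));
    }
  }
  return wr / TWO_PI;
}

// [[Rcpp::export]]
double cpp_linking_number(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  Coords A = from_matrix(a), B = from_matrix(b);
  double lk = 0.0;
  for (int i = 0; i < na; ++i) {
    int i2 = (i + 1) % na;
    for (int j = 0; j < nb; ++j) {
      int j2 = (j + 1) % nb;
      lk += segment_pair_omega(A.p(i), A.p(i2), B.p(j), B.p(j2));
    }
  }
  return lk / (2.0 * TWO_PI);
}

// ------------------------------------------------------------- ring threading

// best-fit ring plane (area-vector normal) + centroid + mean radius
static void ring_plane(const Coords& ring, double* centre, double* normal,
                       double* radius) {
  int m = ring.n;
  for (int q = 0; q < 3; ++q) centre[q] = 0.0;
  for (int i = 0; i < m; ++i)
    for (int q = 0; q < 3; ++q) centre[q] += ring.p(i)[q] / m;
  double nrm[3] = {0, 0, 0};
  for (int i = 0; i < m; ++i) {
    int j = (i + 1) % m;
    double a[3], b[3], c[3];
    for (int q = 0; q < 3; ++q) {
      a[q] = ring.p(i)[q] - centre[q];
      b[q] = ring.p(j)[q] - centre[q];
    }
    cross3(a, b, c);
    for (int q = 0; q < 3; ++q) nrm[q] += c[q];
  }
  double l = norm3(nrm);
  if (l < 1e-12) {
    nrm[0] = 0;
    nrm[1] = 0;
    nrm[2] = 1;
    l = 1;
  }
  for (int q = 0; q < 3; ++q) normal[q] = nrm[q] / l;
  double r = 0.0;
  for (int i = 0; i < m; ++i) {
    double a[3];
    for (int q = 0; q < 3; ++q) a[q] = ring.p(i)[q] - centre[q];
    r += norm3(a) / m;
  }
  *radius = r;
}

// identify the fiber bead threaded through the ring on each arm.
// Returns (c_plus, c_minus) 0-based, or (-1,-1) when fewer than two arms
// pierce the ring. Arms are distinguished by the sign of the local fiber
// direction projected on the ring normal; ties on plane distance break to
// the lower bead index.
static void find_threaded(const Coords& pos, const Coords& ring, bool closed,
                          double axial_window, int* c_plus, int* c_minus,
                          int prev_p = -1, int prev_m = -1,
                          int continuity = 6) {
  int n = pos.n;
  double centre[3], normal[3], radius;
  ring_plane(ring, centre, normal, &radius);
  bool anchored = (prev_p >= 0 && prev_m >= 0);
  double best_d[2] = {1e30, 1e30};
  int best_i[2] = {-1, -1};
  for (int i = 0; i < n; ++i) {
    double d[3];
    for (int q = 0; q < 3; ++q) d[q] = pos.p(i)[q] - centre[q];
    double ax = dot3(d, normal);
    if (std::fabs(ax) > axial_window) continue;
    double inpl2 = dot3(d, d) - ax * ax;
    if (inpl2 > radius * radius) continue;
    if (!closed && (i == 0 || i == n - 1)) continue;
    double ad = std::fabs(ax);
    if (anchored) {
      // the boundary beads move at most a few beads between refreshes:
      // assign each arm by proximity to its previous boundary
      int dp = std::abs(i - prev_p); dp = std::min(dp, n - dp);
      int dm = std::abs(i - prev_m); dm = std::min(dm, n - dm);
      int grp;
      if (dp <= continuity && (dp < dm || (dp == dm && prev_p < prev_m)))
        grp = 0;
      else if (dm <= continuity)
        grp = 1;
      else
        continue;
      if (ad < best_d[grp] - 1e-12 ||
          (std::fabs(ad - best_d[grp]) <= 1e-12 && i < best_i[grp])) {
        best_d[grp] = ad;
        best_i[grp] = i;
      }
    } else {
      // initial detection: arms distinguished by the sign of the local
      // chain direction projected on the ring normal
      int ip = (i + 1) % n, im = (i - 1 + n) % n;
      double t[3];
      for (int q = 0; q < 3; ++q) t[q] = pos.p(ip)[q] - pos.p(im)[q];
      int grp = dot3(t, normal) >= 0 ? 0 : 1;
      if (ad < best_d[grp] - 1e-12 ||
          (std::fabs(ad - best_d[grp]) <= 1e-12 && i < best_i[grp])) {
        best_d[grp] = ad;
        best_i[grp] = i;
      }
    }
  }
  if (best_i[0] == best_i[1]) best_i[1] = -1;
  *c_plus = best_i[0];
  *c_minus = best_i[1];
}

// [[Rcpp::export]]
IntegerVector cpp_threaded_beads(NumericMatrix pos, NumericMatrix ring,
                                 bool closed, double axial_window,
                                 int prev_p = -1, int prev_m = -1) {
  Coords P = from_matrix(pos), R = from_matrix(ring);
  int cp, cm;
  find_threaded(P, R, closed, axial_window, &cp, &cm, prev_p, prev_m);
  return IntegerVector::create(cp, cm);  // 0-based; -1 = not threaded
}

// circular arm lengths from the loading bead; the loop contains the loading
// bead and is bounded by the two threaded beads.
static void arm_sizes(int n, int loading, int ca, int cb, int* arm_p,
                      int* arm_m, int* cp_out, int* cm_out) {
  int dp_a = (ca - loading + n) % n;  // + direction distance to ca
  int dp_b = (cb - loading + n) % n;
  // assign the bead with the smaller +distance as the + arm boundary
  if (dp_a <= dp_b) {
    *cp_out = ca;
    *cm_out = cb;
    *arm_p = dp_a;
    *arm_m = (n - dp_b) % n;
  } else {
    *cp_out = cb;
    *cm_out = ca;
    *arm_p = dp_b;
    *arm_m = (n - dp_a) % n;
  }
}

// ---------------------------------------------------------------- integrator

// [[Rcpp::export]]
List cpp_integrate(NumericMatrix pos_, NumericMatrix pax_, NumericMatrix ring_,
                   NumericVector gamma_bb_, NumericVector gamma_pax_,
                   NumericVector gamma_ring_, IntegerVector torsion_active_,
                   NumericVector phi0_, List params, int n_steps,
                   int frame_interval, int seed, bool motor_on,
                   double steps_per_rotation, double rotation_sign,
                   bool ring_present, double gamma_c, bool nicks_on,
                   bool friction_on, int cap_steps, double start_time,
                   double start_motor_turns, int single_threaded_bead) {
  SysParams sp = parse_params(params);
  Coords pos = from_matrix(pos_), pax = from_matrix(pax_),
         ring = from_matrix(ring_);
  int n = pos.n, m = ring.n;
  int nb = sp.closed ? n : n - 1;
  std::vector<double> gbb(gamma_bb_.begin(), gamma_bb_.end());
  std::vector<double> gpx(gamma_pax_.begin(), gamma_pax_.end());
  std::vector<double> grg(gamma_ring_.begin(), gamma_ring_.end());
  std::vector<int> tors(torsion_active_.begin(), torsion_active_.end());
  std::vector<double> phi0(phi0_.begin(), phi0_.end());
  Coords fp(n), fx(n), fr(m);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  double dt = sp.dt, kT = sp.kT;
  int lb = sp.loading_bead;
  double motor_turns = start_motor_turns;
  double released_lk = 0.0;
  int cp = -1, cm = -1;  // threaded beads (0-based)
  int prev_cp = -1, prev_cm = -1;
  int nick_p = -1, nick_m = -1;  // nicked bond indices
  int patience = 0;
  int complete_count = 0;
  const int max_patience = 2000;
  std::string status = "budget";

  int n_frames_max = n_steps / std::max(1, frame_interval) + 2;
  std::vector<double> tr_time;
  tr_time.reserve(n_frames_max);
  std::vector<double> tr_motor;
  std::vector<int> tr_cp, tr_cm;
  std::vector<double> frames_pos, frames_pax, frames_ring, frames_phi0;
  frames_pos.reserve((size_t)n_frames_max * 3 * n);

  double axial_window = 2.5 * sp.sigma;

  auto record_frame = [&](double t) {
    tr_time.push_back(t);
    tr_motor.push_back(motor_turns);
    tr_cp.push_back(cp);
    tr_cm.push_back(cm);
    frames_pos.insert(frames_pos.end(), pos.x.begin(), pos.x.end());
    frames_pax.insert(frames_pax.end(), pax.x.begin(), pax.x.end());
    if (m > 0) frames_ring.insert(frames_ring.end(), ring.x.begin(), ring.x.end());
    frames_phi0.insert(frames_phi0.end(), phi0.begin(), phi0.end());
  };

  // helper: set/refresh nicks given threaded beads; reactivated bonds get
  // phi0 reset to their instantaneous angle (outside-loop relaxation)
  auto refresh_nicks = [&](void) {
    int new_p = -1, new_m = -1;
    if (cp >= 0 && cm >= 0) {
      int arm_p, arm_m, cpp2, cmm2;
      arm_sizes(n, lb, cp, cm, &arm_p, &arm_m, &cpp2, &cmm2);
      // + arm boundary bead cpp2: first bond outside the loop is (cpp2, cpp2+1)
      new_p = cpp2 % n;
      // - arm boundary bead cmm2: first bond outside is (cmm2-1, cmm2)
      new_m = (cmm2 - 1 + n) % n;
    }
    auto reactivate = [&](int bond) {
      if (bond < 0 || bond >= nb) return;
      int j = (bond + 1) % n;
      bool deg = false;
      double phi = twist_angle_pair(pax.p(bond), pos.p(bond), pos.p(j),
                                    pax.p(j), &deg);
      if (!deg) {
        released_lk += wrap_angle(phi - phi0[bond]) / TWO_PI;
        phi0[bond] = phi;
      }
      tors[bond] = 1;
    };
    if (nick_p != new_p) {
      reactivate(nick_p);
      nick_p = new_p;
      if (nick_p >= 0) tors[nick_p] = 0;
    }
    if (nick_m != new_m) {
      reactivate(nick_m);
      nick_m = new_m;
      if (nick_m >= 0) tors[nick_m] = 0;
    }
  };

  auto refresh_friction = [&](void) {
    auto set_g = [&](int bead, double g) {
      if (bead < 0) return;
      gbb[bead] = g;
      gpx[bead] = g;
    };
    if (prev_cp != cp || prev_cm != cm) {
      set_g(prev_cp, sp.gamma_R);
      set_g(prev_cm, sp.gamma_R);
      if (single_threaded_bead == 1) {
        // single-bead variant: friction only at the + arm bead
        set_g(cp, gamma_c);
        set_g(cm, sp.gamma_R);
      } else {
        set_g(cp, gamma_c);
        set_g(cm, gamma_c);
      }
      prev_cp = cp;
      prev_cm = cm;
    }
  };

  // initial threading
  if (ring_present) {
    find_threaded(pos, ring, sp.closed, axial_window, &cp, &cm);
    if (friction_on) refresh_friction();
    if (nicks_on) refresh_nicks();
  }
  record_frame(start_time);

  double sq = std::sqrt(2.0 * kT * dt);
  int step = 0;
  for (step = 1; step <= n_steps; ++step) {
    double E = all_forces(pos, pax, ring, tors, phi0, sp, fp, fx, fr);
    (void)E;
    double cap = (cap_steps > 0 && step <= cap_steps)
                     ? std::min(100.0, sp.force_cap > 0 ? sp.force_cap : 100.0)
                     : sp.force_cap;
    if (cap > 0) {
      auto capf = [&](Coords& f) {
        for (int i = 0; i < f.n; ++i) {
          double l = norm3(f.p(i));
          if (l > cap) {
            double s = cap / l;
            for (int q = 0; q < 3; ++q) f.p(i)[q] *= s;
          }
        }
      };
      capf(fp);
      capf(fx);
      capf(fr);
    }
    // integration-instability guard on the (capped) displacement
    {
      double worst = 0.0;
      for (int i = 0; i < n; ++i) {
        double l = norm3(fp.p(i)) * dt / gbb[i];
        if (l > worst) worst = l;
      }
      for (int i = 0; i < m; ++i) {
        double l = norm3(fr.p(i)) * dt / grg[i];
        if (l > worst) worst = l;
      }
      if (worst > 0.5 * sp.sigma) {
        status = "unstable";
        record_frame(start_time + step * dt);
        break;
      }
    }
    // overdamped update
    std::vector<double> pos_old(pos.x);
    for (int i = 0; i < n; ++i) {
      double mob = dt / gbb[i], nz = sq / std::sqrt(gbb[i]);
      for (int q = 0; q < 3; ++q)
        pos.p(i)[q] += mob * fp.p(i)[q] + nz * gauss(rng);
    }
    // periaxial beads are ordinary Langevin particles (their forces are
    // all gradients of the potential, so detailed balance holds); the
    // loading bead's frame is the exception while the motor grips it
    for (int i = 0; i < n; ++i) {
      if (motor_on && i == lb) {
        double u[3];
        for (int q = 0; q < 3; ++q) u[q] = pax.p(i)[q] - pos_old[3 * i + q];
        gauss(rng); gauss(rng); gauss(rng);  // keep the stream aligned
        for (int q = 0; q < 3; ++q) pax.p(i)[q] = pos.p(i)[q] + u[q];
        continue;
      }
      double mob = dt / gpx[i], nz = sq / std::sqrt(gpx[i]);
      for (int q = 0; q < 3; ++q)
        pax.p(i)[q] += mob * fx.p(i)[q] + nz * gauss(rng);
    }
    for (int i = 0; i < m; ++i) {
      double mob = dt / grg[i], nz = sq / std::sqrt(grg[i]);
      for (int q = 0; q < 3; ++q)
        ring.p(i)[q] += mob * fr.p(i)[q] + nz * gauss(rng);
    }
    // motor: rotate the loading bead's periaxial frame about the local
    // tangent; the upstream bond's torsional reference co-rotates
    // (polymerase-associated topoisomerase removes the positive twin).
    if (motor_on && lb >= 0) {
      int jn = (lb + 1) % n;
      int jp = (lb - 1 + n) % n;
      int up_bond = (lb - 1 + n) % n;  // bond (lb-1 -> lb)
      double t[3];
      for (int q = 0; q < 3; ++q) t[q] = pos.p(jn)[q] - pos.p(lb)[q];
      double lt = norm3(t);
      if (lt > 1e-12) {
        for (int q = 0; q < 3; ++q) t[q] /= lt;
        bool deg = false;
        double old_up = twist_angle_pair(pax.p(jp), pos.p(jp), pos.p(lb),
                                         pax.p(lb), &deg);
        double ang = -rotation_sign * TWO_PI / steps_per_rotation;
        // Rodrigues rotation of the offset u about t by ang: injects twist of
        // sign rotation_sign into bond (lb -> lb+1)
        double u[3];
        for (int q = 0; q < 3; ++q) u[q] = pax.p(lb)[q] - pos.p(lb)[q];
        double c = std::cos(ang), s = std::sin(ang);
        double txu[3];
        cross3(t, u, txu);
        double tdu = dot3(t, u);
        double ur[3];
        for (int q = 0; q < 3; ++q)
          ur[q] = u[q] * c + txu[q] * s + t[q] * tdu * (1 - c);
        for (int q = 0; q < 3; ++q) pax.p(lb)[q] = pos.p(lb)[q] + ur[q];
        if (!deg && sp.closed) {
          double new_up = twist_angle_pair(pax.p(jp), pos.p(jp), pos.p(lb),
                                           pax.p(lb), &deg);
          if (!deg && tors[up_bond])
            phi0[up_bond] = wrap_angle(phi0[up_bond] +
                                       wrap_angle(new_up - old_up));
        }
        motor_turns += rotation_sign / steps_per_rotation;
      }
    }
    // ring threading / friction / nicks
    if (ring_present) {
      int ncp, ncm;
      find_threaded(pos, ring, sp.closed, axial_window, &ncp, &ncm, cp, cm);
      if (ncp < 0 || ncm < 0) {
        ++patience;
        if (patience > max_patience) {
          status = "escape";
          cp = ncp;
          cm = ncm;
          record_frame(start_time + step * dt);
          break;
        }
      } else {
        patience = 0;
        cp = ncp;
        cm = ncm;
        if (friction_on) refresh_friction();
        if (nicks_on) refresh_nicks();
        int arm_p, arm_m, a, b;
        arm_sizes(n, lb, cp, cm, &arm_p, &arm_m, &a, &b);
        if (arm_p + arm_m >= n - 2) {
          if (++complete_count >= 500) {
            status = "complete";
            record_frame(start_time + step * dt);
            break;
          }
        } else {
          complete_count = 0;
        }
      }
    }
    if (step % frame_interval == 0) record_frame(start_time + step * dt);
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  int nf = tr_time.size();
  NumericVector times(tr_time.begin(), tr_time.end());
  NumericVector motor_v(tr_motor.begin(), tr_motor.end());
  IntegerVector cps(tr_cp.begin(), tr_cp.end());
  IntegerVector cms(tr_cm.begin(), tr_cm.end());
  NumericVector fpv(frames_pos.begin(), frames_pos.end());
  NumericVector fxv(frames_pax.begin(), frames_pax.end());
  NumericVector frv(frames_ring.begin(), frames_ring.end());
  NumericVector fph(frames_phi0.begin(), frames_phi0.end());
  fpv.attr("dim") = IntegerVector::create(3, n, nf);
  fxv.attr("dim") = IntegerVector::create(3, n, nf);
  if (m > 0) frv.attr("dim") = IntegerVector::create(3, m, nf);
  fph.attr("dim") = IntegerVector::create(nb, nf);

  return List::create(
      _["times"] = times, _["motor_turns"] = motor_v, _["threaded_plus"] = cps,
      _["threaded_minus"] = cms, _["frames_pos"] = fpv, _["frames_pax"] = fxv,
      _["frames_ring"] = frv, _["frames_phi0"] = fph,
      _["final_pos"] = to_matrix(pos),
      _["final_pax"] = to_matrix(pax), _["final_ring"] = to_matrix(ring),
      _["gamma_bb"] = NumericVector(gbb.begin(), gbb.end()),
      _["gamma_pax"] = NumericVector(gpx.begin(), gpx.end()),
      _["torsion_active"] = IntegerVector(tors.begin(), tors.end()),
      _["phi0"] = NumericVector(phi0.begin(), phi0.end()),
      _["released_lk"] = released_lk, _["status"] = status,
      _["steps_done"] = std::min(step, n_steps),
      _["end_time"] = tr_time[nf - 1], _["end_motor_turns"] = motor_turns);
}

// distance-threshold contact accumulation for one frame
// [[Rcpp::export]]
void cpp_accumulate_contacts(NumericMatrix pos, double cutoff,
                             NumericMatrix acc) {
  int n = pos.nrow();
  Coords P = from_matrix(pos);
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    acc(i, i) += 1.0;
    for (int j = i + 1; j < n; ++j) {
      double d[3];
      for (int q = 0; q < 3; ++q) d[q] = P.p(j)[q] - P.p(i)[q];
      if (dot3(d, d) < c2) {
        acc(i, j) += 1.0;
        acc(j, i) += 1.0;
      }
    }
  }
}
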