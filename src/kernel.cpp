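// Core numerical kernel: the SUGRES-1P effective energy with analytic
// gradients on the anchor coordinates, and the BAOAB Langevin integrator.
// Units: Angstrom, kcal/mol, amu, elementary charges, Kelvin, femtoseconds.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KE_COUL = 332.0716;     // kcal A / (mol e^2)
static const double KB = 0.0019872041;      // kcal / (mol K)
static const double ACC = 4.184e-4;         // (kcal/mol/A/amu) -> A/fs^2

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Params {
  double sigma0_tail, eps_tail, chi_gb, chi_gb_prime;
  double sigma_head, eps_head, born_radius, eps_in, eps_out;
  double alpha1, alpha2, chi_cav_1, chi_cav_2;
  double sigma_iso, eps_cav_iso, eps_cav_tail, cav_width;
  double kappa;
  double w[10];           // bond ang tor GBerne polGB pol caviso cavtail vdw eel
  double temperature, T0;
  double d0, k_bond, theta0, k_angle, k_tor, gamma0;
  double head_offset, tail_offset, site_mass;
  int exclude_near;
};

enum Term { BOND = 0, ANG, TOR, GBERNE, POLGB, POL, CAVISO, CAVTAIL, VDW, EEL, NTERM };

static Params parse_params(const List& pl) {
  Params p;
  p.sigma0_tail = pl["sigma0_tail"]; p.eps_tail = pl["eps_tail"];
  p.chi_gb = pl["chi_gb"]; p.chi_gb_prime = pl["chi_gb_prime"];
  p.sigma_head = pl["sigma_head"]; p.eps_head = pl["eps_head"];
  p.born_radius = pl["born_radius"]; p.eps_in = pl["eps_in"]; p.eps_out = pl["eps_out"];
  p.alpha1 = pl["alpha1"]; p.alpha2 = pl["alpha2"];
  p.chi_cav_1 = pl["chi_cav_1"]; p.chi_cav_2 = pl["chi_cav_2"];
  p.sigma_iso = pl["sigma_iso"]; p.eps_cav_iso = pl["eps_cav_iso"];
  p.eps_cav_tail = pl["eps_cav_tail"]; p.cav_width = pl["cav_width"];
  p.kappa = pl["kappa"];
  NumericVector w = pl["weights"];
  for (int k = 0; k < 10; ++k) p.w[k] = w[k];
  p.temperature = pl["temperature"]; p.T0 = pl["T0"];
  p.d0 = pl["d0"]; p.k_bond = pl["k_bond"];
  p.theta0 = pl["theta0"]; p.k_angle = pl["k_angle"];
  p.k_tor = pl["k_tor"]; p.gamma0 = pl["gamma0"];
  p.head_offset = pl["head_offset"]; p.tail_offset = pl["tail_offset"];
  p.site_mass = pl["site_mass"]; p.exclude_near = pl["exclude_near"];
  return p;
}

// temperature factor f_n(T): 1 for bonded terms (order 1); order 2 for all
// inter-residue pair terms, f_2(T) = ln(e + 1/e) / ln(exp(T/T0) + exp(-T/T0))
static double temp_factor_order(int order, double T, double T0) {
  if (order <= 1) return 1.0;
  double y = std::pow(T / T0, order - 1);
  return std::log(std::exp(1.0) + std::exp(-1.0)) /
         std::log(std::exp(y) + std::exp(-y));
}

static int term_order(int term) {
  return (term == BOND || term == ANG || term == TOR) ? 1 : 2;
}

// ---- per-site geometry and gradient plumbing -------------------------------

struct Geometry {
  int n;                       // anchors
  int dp;                      // sites
  std::vector<Vec3> A;         // anchors
  std::vector<Vec3> u;         // site axes (unit bond vectors)
  std::vector<double> d;       // bond lengths
  std::vector<Vec3> site, head, tail;
};

static bool build_geometry(const std::vector<Vec3>& A, const Params& p, Geometry& g) {
  g.n = (int)A.size();
  g.dp = g.n - 1;
  g.A = A;
  g.u.resize(g.dp); g.d.resize(g.dp);
  g.site.resize(g.dp); g.head.resize(g.dp); g.tail.resize(g.dp);
  for (int s = 0; s < g.dp; ++s) {
    Vec3 b = A[s + 1] - A[s];
    double dd = norm(b);
    if (dd < 1e-10) return false;
    g.d[s] = dd;
    g.u[s] = b * (1.0 / dd);
    g.site[s] = (A[s] + A[s + 1]) * 0.5;
    g.head[s] = g.site[s] + g.u[s] * p.head_offset;
    g.tail[s] = g.site[s] + g.u[s] * p.tail_offset;
  }
  return true;
}

// gradient at a point (site_s + offset * u_s), pushed onto anchors s, s+1
static void add_point_grad(std::vector<Vec3>& grad, const Geometry& g,
                           int s, const Vec3& gv, double offset) {
  Vec3 perp = gv - g.u[s] * dot(g.u[s], gv);
  Vec3 t = perp * (offset / g.d[s]);
  grad[s] += gv * 0.5 - t;
  grad[s + 1] += gv * 0.5 + t;
}

// gradient with respect to the (unit) site axis u_s
static void add_axis_grad(std::vector<Vec3>& grad, const Geometry& g,
                          int s, const Vec3& hv) {
  Vec3 perp = hv - g.u[s] * dot(g.u[s], hv);
  Vec3 t = perp * (1.0 / g.d[s]);
  grad[s] -= t;
  grad[s + 1] += t;
}

// ---- energy terms ----------------------------------------------------------

// Gay-Berne S function and partials
struct Sparts { double S, dSda, dSdb, dSdc; };
static Sparts gb_S(double a, double b, double c, double chi) {
  Sparts o;
  double pm = 1.0 + chi * c, mm = 1.0 - chi * c;
  double ab = a + b, amb = a - b;
  o.S = ab * ab / pm + amb * amb / mm;
  o.dSda = 2.0 * ab / pm + 2.0 * amb / mm;
  o.dSdb = 2.0 * ab / pm - 2.0 * amb / mm;
  o.dSdc = -chi * ab * ab / (pm * pm) + chi * amb * amb / (mm * mm);
  return o;
}

struct PairScalars { double E, dEdr, dEda, dEdb, dEdc; };

// anisotropic Gay-Berne between tails; isotropic LJ when chi = chi' = 0
static PairScalars gay_berne_scal(double r, double a, double b, double c, const Params& p) {
  PairScalars o; o.dEda = o.dEdb = o.dEdc = 0.0;
  double s0 = p.sigma0_tail, e0 = p.eps_tail;
  double chi = p.chi_gb, chip = p.chi_gb_prime;
  double sigma = s0, dsig_da = 0, dsig_db = 0, dsig_dc = 0;
  double eps = e0, deps_da = 0, deps_db = 0, deps_dc = 0;
  if (chi != 0.0 || chip != 0.0) {
    Sparts Sx = gb_S(a, b, c, chi);
    double gg = 1.0 - 0.5 * chi * Sx.S;
    if (gg < 1e-8) { o.E = R_PosInf; o.dEdr = 0; return o; }
    sigma = s0 / std::sqrt(gg);
    double dsdS = 0.25 * chi * sigma * sigma * sigma / (s0 * s0);
    dsig_da = dsdS * Sx.dSda; dsig_db = dsdS * Sx.dSdb; dsig_dc = dsdS * Sx.dSdc;
    double e1 = 1.0 / std::sqrt(std::max(1.0 - chi * chi * c * c, 1e-12));
    Sparts Sp = gb_S(a, b, c, chip);
    double e2 = 1.0 - 0.5 * chip * Sp.S;
    eps = e0 * e1 * e2 * e2;
    double de1_dc = chi * chi * c * e1 * e1 * e1;
    deps_da = -e0 * e1 * e2 * chip * Sp.dSda;
    deps_db = -e0 * e1 * e2 * chip * Sp.dSdb;
    deps_dc = e0 * (de1_dc * e2 * e2 - e1 * e2 * chip * Sp.dSdc);
  }
  double rho = (r - sigma + s0) / s0;
  if (rho <= 1e-8) { o.E = R_PosInf; o.dEdr = 0; return o; }
  double ir6 = std::pow(rho, -6.0), ir12 = ir6 * ir6;
  double shape = ir12 - ir6;
  o.E = 4.0 * eps * shape;
  double dEdrho = 4.0 * eps * (-12.0 * ir12 + 6.0 * ir6) / rho;
  o.dEdr = dEdrho / s0;
  double dEdeps = 4.0 * shape;
  double dEdsig = -dEdrho / s0;
  o.dEda = dEdeps * deps_da + dEdsig * dsig_da;
  o.dEdb = dEdeps * deps_db + dEdsig * dsig_db;
  o.dEdc = dEdeps * deps_dc + dEdsig * dsig_dc;
  return o;
}

// anisotropic cavity (desolvation shell) between tails
static PairScalars cav_tail_scal(double r, double a, double b, double c, const Params& p) {
  PairScalars o; o.dEda = o.dEdb = o.dEdc = 0.0;
  double s0 = p.sigma0_tail, w = p.cav_width, A0 = p.eps_cav_tail;
  double sigma = s0, dsdS = 0.0;
  Sparts Sc;
  bool aniso = (p.chi_cav_1 != 0.0);
  if (aniso) {
    Sc = gb_S(a, b, c, p.chi_cav_2);
    double gg = 1.0 - 0.5 * p.chi_cav_1 * Sc.S;
    if (gg < 1e-8) { o.E = R_PosInf; o.dEdr = 0; return o; }
    sigma = s0 / std::sqrt(gg);
    dsdS = 0.25 * p.chi_cav_1 * sigma * sigma * sigma / (s0 * s0);
  }
  double x = r - sigma;
  double E = A0 * std::exp(-x * x / (2.0 * w * w));
  o.E = E;
  o.dEdr = -E * x / (w * w);
  if (aniso) {
    double dEdsig = E * x / (w * w);
    o.dEda = dEdsig * dsdS * Sc.dSda;
    o.dEdb = dEdsig * dsdS * Sc.dSdb;
    o.dEdc = dEdsig * dsdS * Sc.dSdc;
  }
  return o;
}

// Still's generalized Born interpolation
static double fgb(double r, double aij, double* dfdr) {
  double ex = std::exp(-r * r / (4.0 * aij));
  double f = std::sqrt(r * r + aij * ex);
  if (dfdr) *dfdr = r * (1.0 - 0.25 * ex) / f;
  return f;
}

// distance-only scalar terms: return E and dE/dr
static void polgb_scal(double r, double qi, double qj, const Params& p,
                       double* E, double* dEdr) {
  double aij = p.born_radius * p.born_radius;
  double df;
  double f = fgb(r, aij, &df);
  double C = KE_COUL * (1.0 / p.eps_in - 1.0 / p.eps_out) * qi * qj;
  *E = -C / f;
  *dEdr = C * df / (f * f);
}

static void pol_part_scal(double r, double q, const Params& p,
                          double* E, double* dEdr) {
  // induced polarization of an uncharged tail by a screened charged head:
  // -C (alpha1 q^2 e^{-2 kr}(1+kr)^2 / r^4 + alpha2 q^2 e^{-2 kr} / r^6)
  double k = p.kappa;
  double C = (1.0 / p.eps_in - 1.0 / p.eps_out) * q * q;
  double ex = std::exp(-2.0 * k * r);
  double okr = 1.0 + k * r;
  double r4 = r * r * r * r, r6 = r4 * r * r;
  double P4 = ex * okr * okr / r4;
  double P6 = ex / r6;
  double dP4 = ex * (-2.0 * k * okr * okr + 2.0 * k * okr) / r4
               - 4.0 * ex * okr * okr / (r4 * r);
  double dP6 = ex * (-2.0 * k) / r6 - 6.0 * ex / (r6 * r);
  *E = -C * (p.alpha1 * P4 + p.alpha2 * P6);
  *dEdr = -C * (p.alpha1 * dP4 + p.alpha2 * dP6);
}

static void caviso_scal(double r, const Params& p, double* E, double* dEdr) {
  double s = 2.0 * p.sigma_iso, w = p.cav_width;
  double x = r - s;
  double e = p.eps_cav_iso * std::exp(-x * x / (2.0 * w * w));
  *E = e;
  *dEdr = -e * x / (w * w);
}

static void lj_scal(double r, const Params& p, double* E, double* dEdr) {
  double sr6 = std::pow(p.sigma_head / r, 6.0);
  *E = 4.0 * p.eps_head * (sr6 * sr6 - sr6);
  *dEdr = 4.0 * p.eps_head * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
}

static void eel_scal(double r, double qi, double qj, const Params& p,
                     double* E, double* dEdr) {
  double e = KE_COUL * qi * qj * std::exp(-p.kappa * r) / (p.eps_in * r);
  *E = e;
  *dEdr = e * (-p.kappa - 1.0 / r);
}

// ---- full evaluation -------------------------------------------------------

struct Report {
  double raw[NTERM];      // unweighted, unfactored per-term sums
  double total;           // sum_k w_k f_k raw_k
  std::vector<Vec3> force; // -gradient of total, on anchors
  bool finite;
};

static void eval_all(const Geometry& g, const std::vector<double>& q,
                     const Params& p, bool want_forces, Report& rep) {
  int n = g.n, dp = g.dp;
  for (int k = 0; k < NTERM; ++k) rep.raw[k] = 0.0;
  rep.total = R_PosInf;
  rep.finite = false;
  if (want_forces) rep.force.assign(n, Vec3());
  std::vector<Vec3> grad(want_forces ? n : 0);
  double wf[NTERM];
  for (int k = 0; k < NTERM; ++k) {
    wf[k] = p.w[k] * temp_factor_order(term_order(k), p.temperature, p.T0);
  }
  const double th0 = p.theta0 * M_PI / 180.0;
  const double g0 = p.gamma0 * M_PI / 180.0;

  // bonds
  for (int s = 0; s < dp; ++s) {
    double dd = g.d[s] - p.d0;
    rep.raw[BOND] += 0.5 * p.k_bond * dd * dd;
    if (want_forces) {
      Vec3 gv = g.u[s] * (wf[BOND] * p.k_bond * dd);
      grad[s] -= gv;
      grad[s + 1] += gv;
    }
  }

  // virtual-bond angles (vertex anchors 1..n-2); cache theta and gradients
  std::vector<double> theta(std::max(n - 2, 0));
  std::vector<Vec3> dth1(std::max(n - 2, 0)), dth2(std::max(n - 2, 0));
  for (int v = 1; v <= n - 2; ++v) {
    Vec3 v1 = g.A[v - 1] - g.A[v];
    Vec3 v2 = g.A[v + 1] - g.A[v];
    double l1 = norm(v1), l2 = norm(v2);
    double x = dot(v1, v2) / (l1 * l2);
    x = std::max(-1.0 + 1e-12, std::min(1.0 - 1e-12, x));
    double th = std::acos(x);
    theta[v - 1] = th;
    double dd = th - th0;
    rep.raw[ANG] += 0.5 * p.k_angle * dd * dd;
    double dacos = -1.0 / std::sqrt(1.0 - x * x);
    Vec3 dxdv1 = (v2 * (1.0 / (l1 * l2))) - v1 * (x / (l1 * l1));
    Vec3 dxdv2 = (v1 * (1.0 / (l1 * l2))) - v2 * (x / (l2 * l2));
    dth1[v - 1] = dxdv1 * dacos;   // d theta / d A[v-1]
    dth2[v - 1] = dxdv2 * dacos;   // d theta / d A[v+1]
    if (want_forces) {
      double s = wf[ANG] * p.k_angle * dd;
      grad[v - 1] += dth1[v - 1] * s;
      grad[v + 1] += dth2[v - 1] * s;
      grad[v] -= (dth1[v - 1] + dth2[v - 1]) * s;
    }
  }

  // torsions: U = k_tor sin(theta_a) sin(theta_b) (1 - cos(gamma - gamma0))
  for (int t = 0; t + 3 < n; ++t) {
    Vec3 b1 = g.A[t + 1] - g.A[t];
    Vec3 b2 = g.A[t + 2] - g.A[t + 1];
    Vec3 b3 = g.A[t + 3] - g.A[t + 2];
    Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
    double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
    double lb2 = norm(b2);
    double tha = theta[t], thb = theta[t + 1];
    double sa = std::sin(tha), sb = std::sin(thb);
    double gamma;
    if (n1sq < 1e-14 || n2sq < 1e-14) {
      gamma = M_PI;   // degenerate: extended by convention; sin factors ~ 0
    } else {
      Vec3 b2n = b2 * (1.0 / lb2);
      gamma = std::atan2(dot(cross(n1, n2), b2n), dot(n1, n2));
    }
    double one_m_cos = 1.0 - std::cos(gamma - g0);
    rep.raw[TOR] += p.k_tor * sa * sb * one_m_cos;
    if (want_forces && n1sq > 1e-14 && n2sq > 1e-14) {
      double w = wf[TOR] * p.k_tor;
      double dUdg = w * sa * sb * std::sin(gamma - g0);
      double dUdta = w * std::cos(tha) * sb * one_m_cos;
      double dUdtb = w * sa * std::cos(thb) * one_m_cos;
      // dihedral gradients (Blondel-Karplus form)
      Vec3 g1 = n1 * (-lb2 / n1sq);
      Vec3 g4 = n2 * (lb2 / n2sq);
      double c12 = dot(b1, b2) / (lb2 * lb2);
      double c32 = dot(b3, b2) / (lb2 * lb2);
      Vec3 g2 = g1 * (-c12 - 1.0) + g4 * c32;
      Vec3 g3 = (g1 + g2 + g4) * (-1.0);
      grad[t] += g1 * dUdg;
      grad[t + 1] += g2 * dUdg;
      grad[t + 2] += g3 * dUdg;
      grad[t + 3] += g4 * dUdg;
      // theta_a spans anchors t, t+1, t+2 (vertex t+1)
      grad[t] += dth1[t] * dUdta;
      grad[t + 2] += dth2[t] * dUdta;
      grad[t + 1] -= (dth1[t] + dth2[t]) * dUdta;
      // theta_b spans anchors t+1, t+2, t+3 (vertex t+2)
      grad[t + 1] += dth1[t + 1] * dUdtb;
      grad[t + 3] += dth2[t + 1] * dUdtb;
      grad[t + 2] -= (dth1[t + 1] + dth2[t + 1]) * dUdtb;
    }
  }

  // non-bonded site pairs
  double ho = p.head_offset, to = p.tail_offset;
  for (int i = 0; i < dp; ++i) {
    for (int j = i + 1; j < dp; ++j) {
      if (j - i <= p.exclude_near) continue;

      // --- tail-tail: Gay-Berne + anisotropic cavity
      Vec3 rv = g.tail[j] - g.tail[i];
      double r = norm(rv);
      if (r < 1e-10) { rep.finite = false; return; }
      Vec3 rhat = rv * (1.0 / r);
      double a = dot(rhat, g.u[i]);
      double b = dot(rhat, g.u[j]);
      double c = dot(g.u[i], g.u[j]);

      PairScalars gb = gay_berne_scal(r, a, b, c, p);
      PairScalars cv = cav_tail_scal(r, a, b, c, p);
      rep.raw[GBERNE] += gb.E;
      rep.raw[CAVTAIL] += cv.E;
      if (want_forces) {
        double wa = wf[GBERNE], wb = wf[CAVTAIL];
        double dEdr = wa * gb.dEdr + wb * cv.dEdr;
        double dEda = wa * gb.dEda + wb * cv.dEda;
        double dEdb = wa * gb.dEdb + wb * cv.dEdb;
        double dEdc = wa * gb.dEdc + wb * cv.dEdc;
        Vec3 gR = rhat * dEdr
                + (g.u[i] - rhat * a) * (dEda / r)
                + (g.u[j] - rhat * b) * (dEdb / r);
        Vec3 gU1 = rhat * dEda + g.u[j] * dEdc;
        Vec3 gU2 = rhat * dEdb + g.u[i] * dEdc;
        add_point_grad(grad, g, i, gR * (-1.0), to);
        add_point_grad(grad, g, j, gR, to);
        add_axis_grad(grad, g, i, gU1);
        add_axis_grad(grad, g, j, gU2);
      }

      // --- head-head: GB polarization + isotropic cavity + LJ + electrostatics
      Vec3 hv = g.head[j] - g.head[i];
      double rh = norm(hv);
      if (rh < 1e-10) { rep.finite = false; return; }
      Vec3 hhat = hv * (1.0 / rh);
      double E1, D1, E2, D2, E3, D3, E4, D4;
      polgb_scal(rh, q[i], q[j], p, &E1, &D1);
      caviso_scal(rh, p, &E2, &D2);
      lj_scal(rh, p, &E3, &D3);
      eel_scal(rh, q[i], q[j], p, &E4, &D4);
      rep.raw[POLGB] += E1;
      rep.raw[CAVISO] += E2;
      rep.raw[VDW] += E3;
      rep.raw[EEL] += E4;
      if (want_forces) {
        double dEdr = wf[POLGB] * D1 + wf[CAVISO] * D2 + wf[VDW] * D3 + wf[EEL] * D4;
        Vec3 gR = hhat * dEdr;
        add_point_grad(grad, g, i, gR * (-1.0), ho);
        add_point_grad(grad, g, j, gR, ho);
      }

      // --- head-tail polarization: head i with tail j, head j with tail i
      Vec3 c1 = g.tail[j] - g.head[i];
      Vec3 c2 = g.tail[i] - g.head[j];
      double r1 = norm(c1), r2 = norm(c2);
      if (r1 < 1e-10 || r2 < 1e-10) { rep.finite = false; return; }
      double Ep1, Dp1, Ep2, Dp2;
      pol_part_scal(r1, q[i], p, &Ep1, &Dp1);
      pol_part_scal(r2, q[j], p, &Ep2, &Dp2);
      rep.raw[POL] += Ep1 + Ep2;
      if (want_forces) {
        Vec3 g1v = c1 * (wf[POL] * Dp1 / r1);   // gradient at tail_j
        add_point_grad(grad, g, j, g1v, to);
        add_point_grad(grad, g, i, g1v * (-1.0), ho);
        Vec3 g2v = c2 * (wf[POL] * Dp2 / r2);   // gradient at tail_i
        add_point_grad(grad, g, i, g2v, to);
        add_point_grad(grad, g, j, g2v * (-1.0), ho);
      }
    }
  }

  rep.total = 0.0;
  rep.finite = true;
  for (int k = 0; k < NTERM; ++k) {
    rep.total += wf[k] * rep.raw[k];
    if (!std::isfinite(rep.raw[k])) rep.finite = false;
  }
  if (want_forces) {
    for (int k = 0; k < n; ++k) {
      rep.force[k] = grad[k] * (-1.0);
      if (!std::isfinite(grad[k].x) || !std::isfinite(grad[k].y) ||
          !std::isfinite(grad[k].z)) rep.finite = false;
    }
  }
}

static std::vector<Vec3> mat_to_vec(const NumericMatrix& m) {
  std::vector<Vec3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = Vec3(m(i, 0), m(i, 1), m(i, 2));
  return v;
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix anchors, NumericVector charges, List params,
                bool forces = false) {
  Params p = parse_params(params);
  std::vector<Vec3> A = mat_to_vec(anchors);
  Geometry g;
  if (!build_geometry(A, p, g)) stop("singular geometry: coincident anchors");
  if ((int)charges.size() != g.dp) stop("charge count must equal dp");
  std::vector<double> q(charges.begin(), charges.end());
  Report rep;
  eval_all(g, q, p, forces, rep);
  NumericVector raw(NTERM), ff(NTERM), ww(NTERM);
  CharacterVector nm = CharacterVector::create(
    "bond", "ang", "tor", "GBerne", "polGB", "pol",
    "caviso", "cavtail", "vdw", "eel");
  for (int k = 0; k < NTERM; ++k) {
    raw[k] = rep.raw[k];
    ff[k] = temp_factor_order(term_order(k), p.temperature, p.T0);
    ww[k] = p.w[k];
  }
  raw.names() = nm; ff.names() = nm; ww.names() = nm;
  List out = List::create(
    _["raw"] = raw, _["f_factors"] = ff, _["weights"] = ww,
    _["total"] = rep.total, _["finite"] = rep.finite);
  if (forces) {
    NumericMatrix F(g.n, 3);
    for (int k = 0; k < g.n; ++k) {
      F(k, 0) = rep.force[k].x; F(k, 1) = rep.force[k].y; F(k, 2) = rep.force[k].z;
    }
    out["forces"] = F;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_temp_factor(int order, double T, double T0) {
  return temp_factor_order(order, T, T0);
}

// ---- Langevin dynamics (BAOAB) --------------------------------------------

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix anchors, NumericVector charges, List params,
                      int n_steps, double dt, double temperature, double friction,
                      int stride, std::string init_velocities, bool remove_com,
                      Nullable<NumericMatrix> velocities0 = R_NilValue) {
  Params p = parse_params(params);
  p.temperature = temperature;
  std::vector<Vec3> X = mat_to_vec(anchors);
  int n = (int)X.size();
  Geometry g;
  if (!build_geometry(X, p, g)) stop("singular geometry: coincident anchors");
  if ((int)charges.size() != g.dp) stop("charge count must equal dp");
  std::vector<double> q(charges.begin(), charges.end());
  double m = p.site_mass;

  std::vector<Vec3> V(n);
  if (velocities0.isNotNull()) {
    NumericMatrix v0(velocities0);
    for (int k = 0; k < n; ++k) V[k] = Vec3(v0(k, 0), v0(k, 1), v0(k, 2));
  } else if (init_velocities == "maxwell") {
    double sd = std::sqrt(KB * temperature * ACC / m);
    for (int k = 0; k < n; ++k) {
      V[k] = Vec3(sd * norm_rand(), sd * norm_rand(), sd * norm_rand());
    }
  } // "zero": all zero

  double gam = friction * 1e-3;   // 1/ps -> 1/fs
  double c1 = std::exp(-gam * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * KB * temperature * ACC / m);
  bool noise = friction > 0.0;

  int n_frames = n_steps / stride + 1;
  NumericMatrix frames(n_frames, 3 * n);
  NumericVector times(n_frames), epot(n_frames), ekin(n_frames);

  Report rep;
  eval_all(g, q, p, true, rep);
  if (!rep.finite) stop("non-finite energy at the initial configuration");

  double ke_acc = 0.0;    // running mean of kinetic energy (per step)
  int frame = 0, last_good = 0;
  bool blown = false;
  int blow_step = -1;

  auto kinetic = [&]() {
    double ke = 0.0;
    for (int k = 0; k < n; ++k) ke += dot(V[k], V[k]);
    return 0.5 * m * ke / ACC;
  };
  auto record = [&](int step) {
    for (int k = 0; k < n; ++k) {
      frames(frame, k) = X[k].x;
      frames(frame, n + k) = X[k].y;
      frames(frame, 2 * n + k) = X[k].z;
    }
    times[frame] = step * dt;
    epot[frame] = rep.total;
    ekin[frame] = kinetic();
    last_good = frame;
    ++frame;
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    double h = 0.5 * dt * ACC / m;
    for (int k = 0; k < n; ++k) V[k] += rep.force[k] * h;       // B
    for (int k = 0; k < n; ++k) X[k] += V[k] * (0.5 * dt);      // A
    if (noise) {                                                // O
      for (int k = 0; k < n; ++k) {
        V[k] = V[k] * c1 + Vec3(c2 * norm_rand(), c2 * norm_rand(), c2 * norm_rand());
      }
    }
    for (int k = 0; k < n; ++k) X[k] += V[k] * (0.5 * dt);      // A
    if (!build_geometry(X, p, g)) { blown = true; blow_step = step; break; }
    eval_all(g, q, p, true, rep);
    if (!rep.finite) { blown = true; blow_step = step; break; }
    for (int k = 0; k < n; ++k) V[k] += rep.force[k] * h;       // B

    ke_acc += kinetic();

    if (step % stride == 0) {
      if (remove_com) {       // recentre the COM position (energies invariant)
        Vec3 com;
        for (int k = 0; k < n; ++k) com += X[k];
        com = com * (1.0 / n);
        for (int k = 0; k < n; ++k) X[k] -= com;
      }
      record(step);
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  int steps_done = blown ? blow_step - 1 : n_steps;
  double mean_T = steps_done > 0
    ? 2.0 * (ke_acc / steps_done) / (3.0 * n * KB) : NA_REAL;

  NumericMatrix vel(n, 3);
  for (int k = 0; k < n; ++k) {
    vel(k, 0) = V[k].x; vel(k, 1) = V[k].y; vel(k, 2) = V[k].z;
  }
  return List::create(
    _["frames"] = frames, _["times"] = times,
    _["epot"] = epot, _["ekin"] = ekin,
    _["mean_kinetic_T"] = mean_T,
    _["blown_up"] = blown, _["blow_step"] = blow_step,
    _["last_good_frame"] = last_good + 1,  // 1-based for R
    _["n_frames_filled"] = frame,
    _["velocities"] = vel);
}
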