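// Core simulation engine: overdamped bead-spring dynamics of a 2D cell
// (membrane + nucleus loops), dynamic microtubules anchored at a mobile
// centrosome, cortical/perinuclear dynein, microtubule-tip signalling to the
// membrane, and static confinement geometry.
//
// Units: length um, time s, force pN throughout.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <sstream>
#include <string>
#include <limits>

using namespace Rcpp;

static const double WCA_CUT = 1.1224620483093730; // 2^(1/6)

// ---------------------------------------------------------------------------
// Small helpers
// ---------------------------------------------------------------------------

static inline double u01(std::mt19937_64 &g) {
  // uniform in [0,1); fixed 53-bit construction so results are
  // platform-stable and serialization of the engine state is sufficient
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}

static std::string rng_save(const std::mt19937_64 &g) {
  std::ostringstream ss;
  ss << g;
  return ss.str();
}

static void rng_load(std::mt19937_64 &g, const std::string &s) {
  if (s.empty()) return; // default-seeded stream (force-only evaluations)
  std::istringstream ss(s);
  ss >> g;
  if (ss.fail()) stop("invalid RNG state string");
}

// WCA (purely repulsive truncated-shifted Lennard-Jones) force magnitude.
// Positive = repulsive, acting along the separation vector. The magnitude
// saturates at 1.5x the contact value 24*eps/sigma (reached just below
// r = sigma): an explicitly integrated overdamped scheme cannot follow the
// diverging LJ-13 stiffness, and the saturated branch keeps deep-overlap
// forces (and hence per-step displacements) bounded while leaving the force
// law exact over the whole resolved contact range r >~ 0.98*sigma. Overlaps
// below 0.1*sigma are counted for the caller's warning.
static inline double wca_fmag(double r, double sigma, double eps,
                              long *overlaps, double sat_mult = 1.5) {
  double rc = WCA_CUT * sigma;
  if (r >= rc) return 0.0;
  if (r < 0.1 * sigma && overlaps) (*overlaps)++;
  double fsat = sat_mult * 24.0 * eps / sigma;
  double sr = sigma / r;
  double sr2 = sr * sr;
  double sr6 = sr2 * sr2 * sr2;
  double sr7 = sr6 * sr;
  double sr13 = sr6 * sr7;
  double f = 24.0 * eps * (2.0 * sr13 - sr7) / sigma;
  return f > fsat ? fsat : f;
}

static inline double wca_pot(double r, double sigma, double eps) {
  double rc = WCA_CUT * sigma;
  if (r >= rc) return 0.0;
  double rmin = 0.1 * sigma;
  if (r < rmin) r = rmin;
  double sr = sigma / r;
  double sr2 = sr * sr;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  return 4.0 * eps * (sr12 - sr6) + eps;
}

// Harmonic stretch forces along consecutive bonds of a chain or ring.
// Accumulates into fx/fy. Optionally accumulates elastic energy.
static void stretch_accum(const std::vector<double> &x,
                          const std::vector<double> &y, bool closed, double ks,
                          double rest, std::vector<double> &fx,
                          std::vector<double> &fy, double *energy) {
  int n = (int)x.size();
  if (n < 2) return;
  int nb = closed ? n : n - 1;
  for (int i = 0; i < nb; i++) {
    int j = (i + 1) % n;
    double dx = x[j] - x[i], dy = y[j] - y[i];
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < 1e-12) continue; // zero-length bond: no defined direction
    double fm = ks * (r - rest); // >0 when stretched: attraction
    double ux = dx / r, uy = dy / r;
    fx[i] += fm * ux;
    fy[i] += fm * uy;
    fx[j] -= fm * ux;
    fy[j] -= fm * uy;
    if (energy) *energy += 0.5 * ks * (r - rest) * (r - rest);
  }
}

// Discrete worm-like-chain bending: E = kappa/(2*l0) * sum (theta_i - th0)^2
// with theta_i the signed turning angle at vertex i. Rings bend at every
// vertex (th0 = exterior angle of the regular polygon); open chains at
// interior vertices with th0 = 0 and free ends. Analytic gradient.
static void bend_accum(const std::vector<double> &x,
                       const std::vector<double> &y, bool closed, double kappa,
                       double th0, double l0, std::vector<double> &fx,
                       std::vector<double> &fy, double *energy) {
  int n = (int)x.size();
  if (n < 3) return;
  int i0 = closed ? 0 : 1;
  int i1 = closed ? n : n - 1;
  double pref = kappa / l0;
  for (int i = i0; i < i1; i++) {
    int ip = (i - 1 + n) % n;
    int in = (i + 1) % n;
    double ax = x[i] - x[ip], ay = y[i] - y[ip];
    double bx = x[in] - x[i], by = y[in] - y[i];
    double a2 = ax * ax + ay * ay;
    double b2 = bx * bx + by * by;
    if (a2 < 1e-24 || b2 < 1e-24) continue;
    double th = std::atan2(ax * by - ay * bx, ax * bx + ay * by);
    // the 1/|bond| factors in the angle gradient diverge on collapsed
    // bonds (bonded neighbours have no steric core); floor them at a
    // fraction of the rest length so bending forces stay bounded
    double amin = 0.09 * l0 * l0;
    if (a2 < amin) a2 = amin;
    if (b2 < amin) b2 = amin;
    double dth = th - th0;
    // wrap into (-pi, pi]
    while (dth > M_PI) dth -= 2.0 * M_PI;
    while (dth <= -M_PI) dth += 2.0 * M_PI;
    double w = pref * dth; // dE/dtheta
    if (energy) *energy += 0.5 * pref * dth * dth;
    // dtheta = dphi_b - dphi_a with phi the bond angles
    // dphi_a/dx_i = (-ay, ax)/a2 ; dphi_a/dx_ip = (ay, -ax)/a2
    // dphi_b/dx_i = (by, -bx)/b2 ; dphi_b/dx_in = (-by, bx)/b2
    double gipx = -(ay / a2), gipy = (ax / a2);   // -dphi_a/dx_ip
    double gix = (by / b2) - (-ay / a2);          // dtheta/dx_i  (x)
    double giy = (-bx / b2) - (ax / a2);          // dtheta/dx_i  (y)
    double ginx = -(by / b2), giny = (bx / b2);   // dphi_b/dx_in
    // F = -w * dtheta/dx
    fx[ip] -= w * gipx;
    fy[ip] -= w * gipy;
    fx[i] -= w * gix;
    fy[i] -= w * giy;
    fx[in] -= w * ginx;
    fy[in] -= w * giny;
  }
}

// Area elasticity: E = k/2 (A - A0)^2 / A0 on a bead loop, applied through
// the exact shoelace-area gradient (identically zero net force). Represents
// the incompressibility of the enclosed cytoplasm/nucleoplasm.
static void area_accum(const std::vector<double> &x,
                       const std::vector<double> &y, double k, double A0,
                       std::vector<double> &fx, std::vector<double> &fy,
                       double *energy);

// Signed polygon area (shoelace); positive for counter-clockwise winding.
static double polygon_area(const std::vector<double> &x,
                           const std::vector<double> &y) {
  int n = (int)x.size();
  double a = 0.0;
  for (int i = 0; i < n; i++) {
    int j = (i + 1) % n;
    a += x[i] * y[j] - x[j] * y[i];
  }
  return 0.5 * a;
}

static void area_accum(const std::vector<double> &x,
                       const std::vector<double> &y, double k, double A0,
                       std::vector<double> &fx, std::vector<double> &fy,
                       double *energy) {
  if (k <= 0) return;
  int n = (int)x.size();
  double A = polygon_area(x, y); // signed; initial winding is CCW
  double coef = -k * (A - A0) / A0;
  for (int i = 0; i < n; i++) {
    int ip = (i - 1 + n) % n, in = (i + 1) % n;
    fx[i] += coef * 0.5 * (y[in] - y[ip]);
    fy[i] += coef * 0.5 * (x[ip] - x[in]);
  }
  if (energy) *energy += 0.5 * k * (A - A0) * (A - A0) / A0;
}

// Distance from point to segment; also returns unit vector from the closest
// segment point toward the query point.
static inline double seg_dist(double px, double py, double x1, double y1,
                              double x2, double y2, double &ux, double &uy) {
  double dx = x2 - x1, dy = y2 - y1;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 1e-24) {
    t = ((px - x1) * dx + (py - y1) * dy) / L2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  double cx = x1 + t * dx, cy = y1 + t * dy;
  double vx = px - cx, vy = py - cy;
  double d = std::sqrt(vx * vx + vy * vy);
  if (d > 1e-12) {
    ux = vx / d;
    uy = vy / d;
  } else {
    // point on the wall axis: push along the wall normal
    double nl = std::sqrt(L2);
    if (nl > 1e-12) {
      ux = -dy / nl;
      uy = dx / nl;
    } else {
      ux = 1.0;
      uy = 0.0;
    }
  }
  return d;
}

// ---------------------------------------------------------------------------
// Data structures
// ---------------------------------------------------------------------------

struct Pars {
  double Rcell, Rnuc;
  int n_mem, n_nuc, Nmt;
  double sigma_mt, vg, vs, fc, fr;
  double eps_wca, kappa_mt, kappa_mem, kappa_nuc, ks_mem, ks_nuc, ks_mt;
  double k_couple, rest_couple;
  double v_prot0, f_contr0, r_signal;
  double n_sat;   // protrusion saturation (tips per bead)
  double n_sat_c; // contraction saturation (trace units per bead)
  double f_poly; // polymerization force of a sterically stalled growing tip
  double contract_tau;     // decay time of the cortical contraction trace
  double contract_deposit; // deposit rate of shrink-tip signal into the trace
  double deposit_min_contact; // membrane-contact length gating the deposit
  double k_area_mem, k_area_nuc; // area elasticity (cytoplasm/nucleoplasm)
  double A0_mem, A0_nuc;         // rest areas (regular polygon)
  double rho_cortex, rho_nuc, k_on, k_off, v_motor, k_motor, r_capture,
      f_stall;
  double gamma_mem, gamma_nuc, gamma_cen, gamma_mt;
  double dt, v_chemo;
  double rest_mem, rest_nuc, ang_mem, ang_nuc;
};

static Pars read_pars(const List &p) {
  Pars P;
  P.Rcell = as<double>(p["Rcell"]);
  P.Rnuc = as<double>(p["Rnuc"]);
  P.n_mem = as<int>(p["n_mem_beads"]);
  P.n_nuc = as<int>(p["n_nuc_beads"]);
  P.Nmt = as<int>(p["Nmt"]);
  P.sigma_mt = as<double>(p["sigma_mt"]);
  P.vg = as<double>(p["vg"]);
  P.vs = as<double>(p["vs"]);
  P.fc = as<double>(p["fc"]);
  P.fr = as<double>(p["fr"]);
  P.eps_wca = as<double>(p["eps_wca"]);
  P.kappa_mt = as<double>(p["kappa_mt"]);
  P.kappa_mem = as<double>(p["kappa_mem"]);
  P.kappa_nuc = as<double>(p["kappa_nuc"]);
  P.ks_mem = as<double>(p["ks_mem"]);
  P.ks_nuc = as<double>(p["ks_nuc"]);
  P.ks_mt = as<double>(p["ks_mt"]);
  P.k_couple = as<double>(p["k_couple"]);
  P.rest_couple = as<double>(p["rest_couple"]);
  P.v_prot0 = as<double>(p["v_prot0"]);
  P.f_contr0 = as<double>(p["f_contr0"]);
  P.r_signal = as<double>(p["r_signal"]);
  P.n_sat = as<double>(p["n_sat"]);
  P.n_sat_c = as<double>(p["n_sat_contr"]);
  P.f_poly = as<double>(p["f_poly"]);
  P.contract_tau = as<double>(p["contract_tau"]);
  P.contract_deposit = as<double>(p["contract_deposit"]);
  P.deposit_min_contact = as<double>(p["deposit_min_contact"]);
  P.k_area_mem = as<double>(p["k_area_mem"]);
  P.k_area_nuc = as<double>(p["k_area_nuc"]);
  List dy = p["dynein"];
  P.rho_cortex = as<double>(dy["rho_cortex"]);
  P.rho_nuc = as<double>(dy["rho_nuc"]);
  P.k_on = as<double>(dy["k_on"]);
  P.k_off = as<double>(dy["k_off"]);
  P.v_motor = as<double>(dy["v_motor"]);
  P.k_motor = as<double>(dy["k_motor"]);
  P.r_capture = as<double>(dy["r_capture"]);
  P.f_stall = as<double>(dy["f_stall"]);
  P.gamma_mem = as<double>(p["gamma_mem"]);
  P.gamma_nuc = as<double>(p["gamma_nuc"]);
  P.gamma_cen = as<double>(p["gamma_cen"]);
  P.gamma_mt = as<double>(p["gamma_mt"]);
  P.dt = as<double>(p["dt"]);
  P.v_chemo = as<double>(p["v_chemo"]);
  P.A0_mem = 0.5 * P.n_mem * std::sin(2.0 * M_PI / P.n_mem) * P.Rcell *
             P.Rcell;
  P.A0_nuc = 0.5 * P.n_nuc * std::sin(2.0 * M_PI / P.n_nuc) * P.Rnuc * P.Rnuc;
  P.rest_mem = 2.0 * P.Rcell * std::sin(M_PI / P.n_mem);
  P.rest_nuc = 2.0 * P.Rnuc * std::sin(M_PI / P.n_nuc);
  P.ang_mem = 2.0 * M_PI / P.n_mem;
  P.ang_nuc = 2.0 * M_PI / P.n_nuc;
  return P;
}

struct Env {
  std::vector<double> ox, oy, orad;                 // circular obstacles
  std::vector<double> wx1, wy1, wx2, wy2;           // wall segments
  double wall_half;                                 // wall half thickness
  double chemo_dx, chemo_dy;                        // chemotaxis direction
  std::vector<double> chx, chy, chdx, chdy, chw;    // channel mouths
};

static Env read_env(const List &e) {
  Env E;
  E.wall_half = 0.25;
  E.chemo_dx = 1.0;
  E.chemo_dy = 0.0;
  if (e.containsElementNamed("obstacles")) {
    DataFrame ob(e["obstacles"]);
    if (ob.nrows() > 0) {
      NumericVector x = ob["x"], y = ob["y"], r = ob["r"];
      E.ox.assign(x.begin(), x.end());
      E.oy.assign(y.begin(), y.end());
      E.orad.assign(r.begin(), r.end());
    }
  }
  if (e.containsElementNamed("walls")) {
    DataFrame w(e["walls"]);
    if (w.nrows() > 0) {
      NumericVector x1 = w["x1"], y1 = w["y1"], x2 = w["x2"], y2 = w["y2"];
      E.wx1.assign(x1.begin(), x1.end());
      E.wy1.assign(y1.begin(), y1.end());
      E.wx2.assign(x2.begin(), x2.end());
      E.wy2.assign(y2.begin(), y2.end());
    }
  }
  if (e.containsElementNamed("wall_half"))
    E.wall_half = as<double>(e["wall_half"]);
  if (e.containsElementNamed("chemo_dir")) {
    NumericVector d(e["chemo_dir"]);
    double nl = std::sqrt(d[0] * d[0] + d[1] * d[1]);
    if (nl > 0) {
      E.chemo_dx = d[0] / nl;
      E.chemo_dy = d[1] / nl;
    }
  }
  if (e.containsElementNamed("channels")) {
    DataFrame ch(e["channels"]);
    if (ch.nrows() > 0) {
      NumericVector mx = ch["mx"], my = ch["my"], dx = ch["dx"], dy = ch["dy"],
          cw = ch["width"];
      for (int i = 0; i < mx.size(); i++) {
        double nl = std::sqrt(dx[i] * dx[i] + dy[i] * dy[i]);
        E.chx.push_back(mx[i]);
        E.chy.push_back(my[i]);
        E.chdx.push_back(dx[i] / nl);
        E.chdy.push_back(dy[i] / nl);
        E.chw.push_back(cw[i]);
      }
    }
  }
  return E;
}

struct MTchain {
  std::vector<double> x, y, fx, fy;
  int state;      // 0 = GROW, 1 = SHRINK
  double partial; // sub-bead growth accumulator in [0, sigma)
  double dir;     // nucleation direction (used while single-bead)
  bool stalled;   // growth sterically blocked this step (tip pressing)
  bool dep_armed; // this retraction deposits contraction (sticky per shrink
                  // phase: armed once the filament has enough cortical
                  // contact, disarmed on regrowth)
};

struct Motor {
  int loop;  // 0 membrane, 1 nucleus
  int bead;  // anchor bead index (0-based)
  int bound; // 0/1
  int mt;    // MT index when bound
  double arc; // arc position along MT from minus end (um)
};

struct BeadRef {
  double x, y;
  int type, own, sub; // own = MT index for type 2, else -1
};

struct World {
  Pars P;
  Env E;
  int nm, nn;
  std::vector<double> mx, my, nx_, ny_;
  double cx, cy;
  std::vector<MTchain> mts;
  std::vector<Motor> motors;
  std::vector<int> cmap; // nucleus bead -> coupled membrane bead
  double t;
  std::mt19937_64 rng_mt, rng_motor;
  // per-step accumulators
  std::vector<double> fmx, fmy, fnx, fny, vmx, vmy;
  double fcx, fcy;
  std::vector<double> norx, nory; // outward membrane normals
  std::vector<int> ngrow, nshrink, ndep;
  std::vector<double> ctrace; // per-bead cortical contraction memory trace
  // reusable scratch for the steric grid and bead gather (avoids per-step
  // allocation in the hot loop)
  std::vector<BeadRef> B;
  std::vector<int> g_cellof, g_count, g_order;
  double px_sum, py_sum; // protrusion velocity resultant
  long overlaps;
  double max_internal_sum;
};

// ---------------------------------------------------------------------------
// Steric interactions
// ---------------------------------------------------------------------------

// Pair eligibility by bead type: 0 mem, 1 nuc, 2 mt, 3 cen.
// MT-MT pairs (same or different filament) are excluded; membrane
// self-avoidance excludes ring-bonded neighbours; centrosome interacts
// sterically with the nucleus only.
static inline bool pair_ok(int ti, int si, int tj, int sj, int nm) {
  if (ti > tj) {
    std::swap(ti, tj);
    std::swap(si, sj);
  }
  if (ti == 0 && tj == 0) {
    int d = std::abs(si - sj);
    return d > 1 && d < nm - 1;
  }
  if (ti == 0 && (tj == 1 || tj == 2)) return true;
  if (ti == 1 && tj == 2) return true;
  if (ti == 1 && tj == 3) return true;
  return false;
}



static void gather_beads(World &W, std::vector<BeadRef> &B) {
  B.clear();
  for (int i = 0; i < W.nm; i++) B.push_back({W.mx[i], W.my[i], 0, -1, i});
  for (int i = 0; i < W.nn; i++) B.push_back({W.nx_[i], W.ny_[i], 1, -1, i});
  for (int m = 0; m < (int)W.mts.size(); m++) {
    MTchain &mt = W.mts[m];
    for (int k = 0; k < (int)mt.x.size(); k++)
      B.push_back({mt.x[k], mt.y[k], 2, m, k});
  }
  B.push_back({W.cx, W.cy, 3, -1, 0});
}

static inline void add_force(World &W, const BeadRef &b, double fx,
                             double fy) {
  switch (b.type) {
  case 0:
    W.fmx[b.sub] += fx;
    W.fmy[b.sub] += fy;
    break;
  case 1:
    W.fnx[b.sub] += fx;
    W.fny[b.sub] += fy;
    break;
  case 2:
    W.mts[b.own].fx[b.sub] += fx;
    W.mts[b.own].fy[b.sub] += fy;
    break;
  default:
    W.fcx += fx;
    W.fcy += fy;
  }
}

static void steric_pair_apply(World &W, const BeadRef &bi, const BeadRef &bj,
                              double *energy) {
  double dx = bi.x - bj.x, dy = bi.y - bj.y;
  double rc = WCA_CUT * W.P.sigma_mt;
  if (std::fabs(dx) >= rc || std::fabs(dy) >= rc) return;
  double r2 = dx * dx + dy * dy;
  if (r2 >= rc * rc || r2 < 1e-24) return;
  double r = std::sqrt(r2);
  double fm = wca_fmag(r, W.P.sigma_mt, W.P.eps_wca, &W.overlaps);
  if (fm == 0.0) return;
  double ux = dx / r, uy = dy / r;
  add_force(W, bi, fm * ux, fm * uy);
  add_force(W, bj, -fm * ux, -fm * uy);
  if (energy) *energy += wca_pot(r, W.P.sigma_mt, W.P.eps_wca);
}

// All internal (bead-bead) steric forces, via a uniform spatial grid of cell
// size equal to the WCA cutoff, or brute-force all-pairs when use_grid=false.
static void steric_pairs(World &W, bool use_grid, double *energy) {
  std::vector<BeadRef> &B = W.B;
  gather_beads(W, B);
  int n = (int)B.size();
  if (!use_grid) {
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++)
        if (pair_ok(B[i].type, B[i].sub, B[j].type, B[j].sub, W.nm))
          steric_pair_apply(W, B[i], B[j], energy);
    return;
  }
  // MT-MT pairs never interact, so the grid holds only loop beads and the
  // centrosome (a handful), and MT beads merely query it; this keeps the
  // cost linear in the number of filament beads even inside dense bundles
  int nloop = W.nm + W.nn + 1; // beads 0..nm-1 mem, nm..nm+nn-1 nuc, last cen
  std::vector<BeadRef> BL;
  BL.reserve(nloop);
  for (int i = 0; i < W.nm; i++) BL.push_back(B[i]);
  for (int i = 0; i < W.nn; i++) BL.push_back(B[W.nm + i]);
  BL.push_back(B[n - 1]); // centrosome (gathered last)
  double cs = WCA_CUT * W.P.sigma_mt;
  double x0 = BL[0].x, y0 = BL[0].y, x1 = x0, y1 = y0;
  for (int i = 1; i < nloop; i++) {
    x0 = std::min(x0, BL[i].x);
    x1 = std::max(x1, BL[i].x);
    y0 = std::min(y0, BL[i].y);
    y1 = std::max(y1, BL[i].y);
  }
  int ncx = (int)((x1 - x0) / cs) + 1;
  int ncy = (int)((y1 - y0) / cs) + 1;
  std::vector<int> &cellof = W.g_cellof, &count = W.g_count,
                   &order = W.g_order;
  cellof.resize(nloop);
  count.assign(ncx * ncy + 1, 0);
  for (int i = 0; i < nloop; i++) {
    int ix = (int)((BL[i].x - x0) / cs);
    int iy = (int)((BL[i].y - y0) / cs);
    if (ix >= ncx) ix = ncx - 1;
    if (iy >= ncy) iy = ncy - 1;
    cellof[i] = iy * ncx + ix;
    count[cellof[i] + 1]++;
  }
  for (int c = 0; c < ncx * ncy; c++) count[c + 1] += count[c];
  order.resize(nloop);
  {
    std::vector<int> pos(count.begin(), count.end() - 1);
    for (int i = 0; i < nloop; i++) order[pos[cellof[i]]++] = i;
  }
  // loop-loop pairs: half-neighbourhood sweep over the small grid
  for (int iy = 0; iy < ncy; iy++) {
    for (int ix = 0; ix < ncx; ix++) {
      int c = iy * ncx + ix;
      for (int a = count[c]; a < count[c + 1]; a++) {
        int i = order[a];
        for (int b = a + 1; b < count[c + 1]; b++) {
          int j = order[b];
          if (pair_ok(BL[i].type, BL[i].sub, BL[j].type, BL[j].sub, W.nm))
            steric_pair_apply(W, BL[i], BL[j], energy);
        }
        const int offs[4][2] = {{1, 0}, {-1, 1}, {0, 1}, {1, 1}};
        for (int q = 0; q < 4; q++) {
          int jx = ix + offs[q][0], jy = iy + offs[q][1];
          if (jx < 0 || jx >= ncx || jy >= ncy) continue;
          int c2 = jy * ncx + jx;
          for (int b = count[c2]; b < count[c2 + 1]; b++) {
            int j = order[b];
            if (pair_ok(BL[i].type, BL[i].sub, BL[j].type, BL[j].sub, W.nm))
              steric_pair_apply(W, BL[i], BL[j], energy);
          }
        }
      }
    }
  }
  // MT beads query the full neighbourhood of the loop grid
  for (int i = W.nm + W.nn; i < n - 1; i++) {
    // clamp into the loop-bead grid: a bead farther than one cell outside
    // the box cannot be within the cutoff of any loop bead
    int ix = (int)((B[i].x - x0) / cs);
    int iy = (int)((B[i].y - y0) / cs);
    if (ix < -1 || ix > ncx || iy < -1 || iy > ncy) continue;
    ix = std::max(0, std::min(ncx - 1, ix));
    iy = std::max(0, std::min(ncy - 1, iy));
    for (int dy = -1; dy <= 1; dy++) {
      int jy = iy + dy;
      if (jy < 0 || jy >= ncy) continue;
      for (int dx = -1; dx <= 1; dx++) {
        int jx = ix + dx;
        if (jx < 0 || jx >= ncx) continue;
        int c2 = jy * ncx + jx;
        for (int b = count[c2]; b < count[c2 + 1]; b++) {
          int j = order[b];
          if (pair_ok(B[i].type, B[i].sub, BL[j].type, BL[j].sub, W.nm))
            steric_pair_apply(W, B[i], BL[j], energy);
        }
      }
    }
  }
}

// Confinement forces: obstacles and walls repel membrane, nucleus and MT
// beads through the same WCA form applied to the gap from the surface, so
// the repulsion onset sits just outside the obstacle/wall surface.
static void boundary_forces(World &W, double *energy) {
  if (W.E.ox.empty() && W.E.wx1.empty()) return;
  std::vector<BeadRef> &B = W.B; // gathered by steric_pairs this step
  if (B.empty()) gather_beads(W, B);
  double rc = WCA_CUT * W.P.sigma_mt;
  double reach = rc + W.E.wall_half;
  size_t nw = W.E.wx1.size();
  // axis-aligned bounding boxes around each wall, expanded by the reach
  std::vector<double> bx0(nw), bx1(nw), by0(nw), by1(nw);
  for (size_t w = 0; w < nw; w++) {
    bx0[w] = std::min(W.E.wx1[w], W.E.wx2[w]) - reach;
    bx1[w] = std::max(W.E.wx1[w], W.E.wx2[w]) + reach;
    by0[w] = std::min(W.E.wy1[w], W.E.wy2[w]) - reach;
    by1[w] = std::max(W.E.wy1[w], W.E.wy2[w]) + reach;
  }
  for (int i = 0; i < (int)B.size(); i++) {
    if (B[i].type == 3) continue; // centrosome stays inside the cell
    for (size_t o = 0; o < W.E.ox.size(); o++) {
      double dx = B[i].x - W.E.ox[o], dy = B[i].y - W.E.oy[o];
      if (std::fabs(dx) > W.E.orad[o] + rc || std::fabs(dy) > W.E.orad[o] + rc)
        continue;
      double d = std::sqrt(dx * dx + dy * dy);
      double g = d - W.E.orad[o];
      if (g >= rc) continue;
      double gg = std::max(g, 0.05 * W.P.sigma_mt);
      // rigid pillars: a 10x force ceiling so crowding pressure cannot
      // squeeze beads through the surface
      double fm = wca_fmag(gg, W.P.sigma_mt, W.P.eps_wca, &W.overlaps, 10.0);
      double ux = (d > 1e-12) ? dx / d : 1.0;
      double uy = (d > 1e-12) ? dy / d : 0.0;
      add_force(W, B[i], fm * ux, fm * uy);
      if (energy) *energy += wca_pot(gg, W.P.sigma_mt, W.P.eps_wca);
    }
    for (size_t w = 0; w < nw; w++) {
      if (B[i].x < bx0[w] || B[i].x > bx1[w] || B[i].y < by0[w] ||
          B[i].y > by1[w])
        continue;
      double ux, uy;
      double d = seg_dist(B[i].x, B[i].y, W.E.wx1[w], W.E.wy1[w], W.E.wx2[w],
                          W.E.wy2[w], ux, uy);
      double g = d - W.E.wall_half;
      if (g >= rc) continue;
      double gg = std::max(g, 0.05 * W.P.sigma_mt);
      double fm = wca_fmag(gg, W.P.sigma_mt, W.P.eps_wca, &W.overlaps, 10.0);
      add_force(W, B[i], fm * ux, fm * uy);
      if (energy) *energy += wca_pot(gg, W.P.sigma_mt, W.P.eps_wca);
    }
  }
}

// Checks that no bead penetrated an obstacle or wall interior.
static bool containment_ok(World &W) {
  std::vector<BeadRef> B;
  gather_beads(W, B);
  for (int i = 0; i < (int)B.size(); i++) {
    for (size_t o = 0; o < W.E.ox.size(); o++) {
      double dx = B[i].x - W.E.ox[o], dy = B[i].y - W.E.oy[o];
      if (dx * dx + dy * dy < W.E.orad[o] * W.E.orad[o]) return false;
    }
    for (size_t w = 0; w < W.E.wx1.size(); w++) {
      double ux, uy;
      double d = seg_dist(B[i].x, B[i].y, W.E.wx1[w], W.E.wy1[w], W.E.wx2[w],
                          W.E.wy2[w], ux, uy);
      if (d < W.E.wall_half) return false;
    }
  }
  return true;
}

// ---------------------------------------------------------------------------
// Microtubule dynamics
// ---------------------------------------------------------------------------

static void mt_dynamic_switch(World &W) {
  double p_cat = 1.0 - std::exp(-W.P.fc * W.P.dt);
  double p_res = 1.0 - std::exp(-W.P.fr * W.P.dt);
  for (size_t m = 0; m < W.mts.size(); m++) {
    double u = u01(W.rng_mt); // one draw per MT per step keeps streams aligned
    MTchain &mt = W.mts[m];
    if (mt.state == 0) {
      if (u < p_cat) mt.state = 1;
    } else {
      if (u < p_res) {
        mt.state = 0;
        mt.dep_armed = false;
      }
    }
  }
}

// True when placing a bead at (x, y) would overlap the steric core of a
// membrane/nucleus bead, obstacle or wall. Discrete tip insertion is the
// only move that could create deep overlap (all other motion is continuous
// against the WCA gradient); polymerization stalls while the insertion site
// is blocked and resumes once the filament has bent or glided clear.
static double insertion_clearance(World &W, double x, double y) {
  double best = 1e9;
  for (int i = 0; i < W.nm; i++) {
    double dx = x - W.mx[i], dy = y - W.my[i];
    best = std::min(best, std::sqrt(dx * dx + dy * dy));
  }
  for (int i = 0; i < W.nn; i++) {
    double dx = x - W.nx_[i], dy = y - W.ny_[i];
    best = std::min(best, std::sqrt(dx * dx + dy * dy));
  }
  for (size_t o = 0; o < W.E.ox.size(); o++) {
    double dx = x - W.E.ox[o], dy = y - W.E.oy[o];
    best = std::min(best, std::sqrt(dx * dx + dy * dy) - W.E.orad[o]);
  }
  for (size_t w = 0; w < W.E.wx1.size(); w++) {
    double ux, uy;
    double d = seg_dist(x, y, W.E.wx1[w], W.E.wy1[w], W.E.wx2[w], W.E.wy2[w],
                        ux, uy);
    best = std::min(best, d - W.E.wall_half);
  }
  return best;
}

static bool insertion_blocked(World &W, double x, double y) {
  // insertion is allowed down to 0.7*sigma: the landing force is bounded by
  // the WCA saturation, and polymerization against an obstacle then keeps
  // generating the (bounded) pushing force that buckles the filament and
  // lets it glide, as an MT pressing the cortex does
  double rb = 0.7 * W.P.sigma_mt;
  double rb2 = rb * rb;
  for (int i = 0; i < W.nm; i++) {
    double dx = x - W.mx[i], dy = y - W.my[i];
    if (dx * dx + dy * dy < rb2) return true;
  }
  for (int i = 0; i < W.nn; i++) {
    double dx = x - W.nx_[i], dy = y - W.ny_[i];
    if (dx * dx + dy * dy < rb2) return true;
  }
  for (size_t o = 0; o < W.E.ox.size(); o++) {
    double dx = x - W.E.ox[o], dy = y - W.E.oy[o];
    double d = std::sqrt(dx * dx + dy * dy);
    if (d - W.E.orad[o] < rb) return true;
  }
  for (size_t w = 0; w < W.E.wx1.size(); w++) {
    double ux, uy;
    double d = seg_dist(x, y, W.E.wx1[w], W.E.wy1[w], W.E.wx2[w], W.E.wy2[w],
                        ux, uy);
    if (d - W.E.wall_half < rb) return true;
  }
  return false;
}

static void mt_advance_tips(World &W) {
  double sg = W.P.sigma_mt;
  for (size_t m = 0; m < W.mts.size(); m++) {
    MTchain &mt = W.mts[m];
    mt.stalled = false;
    if (mt.state == 0) {
      mt.partial += W.P.vg * W.P.dt;
      if (mt.partial >= sg) {
        while (mt.partial >= sg) {
          int nb = (int)mt.x.size();
          double tx, ty;
          if (nb >= 2) {
            tx = mt.x[nb - 1] - mt.x[nb - 2];
            ty = mt.y[nb - 1] - mt.y[nb - 2];
            double tl = std::sqrt(tx * tx + ty * ty);
            if (tl < 1e-12) {
              tx = std::cos(mt.dir);
              ty = std::sin(mt.dir);
            } else {
              tx /= tl;
              ty /= tl;
            }
          } else {
            tx = std::cos(mt.dir);
            ty = std::sin(mt.dir);
          }
          // steered insertion: subunits add where there is space, so a tip
          // meeting an obstacle glides along it. Try the straight
          // continuation, then progressively rotated directions (up to 90
          // degrees, preferring the side with more clearance); if every
          // direction is blocked the tip stalls and presses (f_poly).
          double x0 = mt.x[nb - 1], y0 = mt.y[nb - 1];
          bool placed = false;
          double nx2 = x0 + sg * tx, ny2 = y0 + sg * ty;
          if (!insertion_blocked(W, nx2, ny2)) {
            placed = true;
          } else {
            double a15 = 15.0 * M_PI / 180.0;
            double cp = insertion_clearance(
                W, x0 + sg * (tx * std::cos(a15) - ty * std::sin(a15)),
                y0 + sg * (tx * std::sin(a15) + ty * std::cos(a15)));
            double cm = insertion_clearance(
                W, x0 + sg * (tx * std::cos(a15) + ty * std::sin(a15)),
                y0 + sg * (-tx * std::sin(a15) + ty * std::cos(a15)));
            double sgn = (cp >= cm) ? 1.0 : -1.0;
            for (int ia = 1; ia <= 6 && !placed; ia++) {
              for (int side = 0; side < 2 && !placed; side++) {
                double ang = sgn * (side == 0 ? 1.0 : -1.0) * ia * a15;
                double ca = std::cos(ang), sa = std::sin(ang);
                double cx2 = x0 + sg * (tx * ca - ty * sa);
                double cy2 = y0 + sg * (tx * sa + ty * ca);
                if (!insertion_blocked(W, cx2, cy2)) {
                  nx2 = cx2;
                  ny2 = cy2;
                  placed = true;
                }
              }
            }
          }
          if (!placed) {
            // fully enclosed: hold the accumulator just below one bead;
            // the tip keeps pressing with the polymerization force
            mt.partial = sg * (1.0 - 1e-9);
            mt.stalled = true;
            break;
          }
          mt.x.push_back(nx2);
          mt.y.push_back(ny2);
          mt.fx.push_back(0.0);
          mt.fy.push_back(0.0);
          mt.partial -= sg;
        }
      }
    } else {
      mt.partial -= W.P.vs * W.P.dt;
      while (mt.partial < 0.0) {
        if ((int)mt.x.size() >= 2) {
          mt.x.pop_back();
          mt.y.pop_back();
          mt.fx.pop_back();
          mt.fy.pop_back();
          mt.partial += sg;
        } else {
          // shrunk to the seed bead: re-nucleate in a fresh random direction
          mt.state = 0;
          mt.partial = 0.0;
          mt.dep_armed = false;
          mt.dir = 2.0 * M_PI * u01(W.rng_mt);
          break;
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Crosstalk: tip signals, protrusion, contraction
// ---------------------------------------------------------------------------

static void membrane_normals(World &W) {
  double sgn = polygon_area(W.mx, W.my) >= 0 ? 1.0 : -1.0;
  for (int i = 0; i < W.nm; i++) {
    int ip = (i - 1 + W.nm) % W.nm;
    int in = (i + 1) % W.nm;
    double tx = W.mx[in] - W.mx[ip], ty = W.my[in] - W.my[ip];
    double tl = std::sqrt(tx * tx + ty * ty);
    if (tl < 1e-12) {
      // degenerate tangent: copy the previous bead's normal
      W.norx[i] = W.norx[ip];
      W.nory[i] = W.nory[ip];
      continue;
    }
    // outward normal for CCW winding is (ty, -tx)
    W.norx[i] = sgn * ty / tl;
    W.nory[i] = sgn * -tx / tl;
  }
}

// Contour length of a filament lying within the contact band of the
// membrane (distance < r_signal of some membrane bead), counted on every
// second bead for speed. A shrinking tip deposits contraction signal only
// when its filament has at least deposit_min_contact of such cortical
// contact: retracting gliding arcs sweep contraction along the cortex,
// whereas a tip that merely recedes radially from the membrane does not.
static double membrane_contact_length(World &W, const MTchain &mt) {
  double r2 = W.P.r_signal * W.P.r_signal;
  int nb = (int)mt.x.size();
  // interior-bead rejection by the membrane inner radius (as in
  // tip_signals): recompute the cheap bound here
  double cxm = 0, cym = 0;
  for (int i = 0; i < W.nm; i++) {
    cxm += W.mx[i];
    cym += W.my[i];
  }
  cxm /= W.nm;
  cym /= W.nm;
  double rmin2 = 1e18;
  for (int i = 0; i < W.nm; i++) {
    double dx = W.mx[i] - cxm, dy = W.my[i] - cym;
    double d2 = dx * dx + dy * dy;
    if (d2 < rmin2) rmin2 = d2;
  }
  double rcut = std::sqrt(rmin2) - W.P.r_signal;
  if (rcut < 0) rcut = 0;
  double rcut2 = rcut * rcut;
  int hits = 0;
  for (int k = 0; k < nb; k += 2) {
    double ddx = mt.x[k] - cxm, ddy = mt.y[k] - cym;
    if (ddx * ddx + ddy * ddy < rcut2) continue;
    for (int i = 0; i < W.nm; i++) {
      double dx = mt.x[k] - W.mx[i], dy = mt.y[k] - W.my[i];
      if (dx * dx + dy * dy < r2) {
        hits++;
        break;
      }
    }
  }
  return hits * 2.0 * W.P.sigma_mt;
}

static void tip_signals(World &W) {
  double r2 = W.P.r_signal * W.P.r_signal;
  std::fill(W.ngrow.begin(), W.ngrow.end(), 0);
  std::fill(W.nshrink.begin(), W.nshrink.end(), 0);
  std::fill(W.ndep.begin(), W.ndep.end(), 0);
  // interior-tip rejection: a tip closer to the membrane centroid than the
  // smallest membrane radius minus r_signal cannot reach any bead
  double cxm = 0, cym = 0;
  for (int i = 0; i < W.nm; i++) {
    cxm += W.mx[i];
    cym += W.my[i];
  }
  cxm /= W.nm;
  cym /= W.nm;
  double rmin2 = 1e18;
  for (int i = 0; i < W.nm; i++) {
    double dx = W.mx[i] - cxm, dy = W.my[i] - cym;
    double d2 = dx * dx + dy * dy;
    if (d2 < rmin2) rmin2 = d2;
  }
  double rcut = std::sqrt(rmin2) - W.P.r_signal;
  if (rcut < 0) rcut = 0;
  double rcut2 = rcut * rcut;
  for (size_t m = 0; m < W.mts.size(); m++) {
    MTchain &mt = W.mts[m];
    int nb = (int)mt.x.size();
    double tx = mt.x[nb - 1], ty = mt.y[nb - 1];
    {
      double dx = tx - cxm, dy = ty - cym;
      if (dx * dx + dy * dy < rcut2) continue; // interior tip, no signal
    }
    bool near = false;
    for (int i = 0; i < W.nm; i++) {
      double dx = tx - W.mx[i], dy = ty - W.my[i];
      if (dx * dx + dy * dy < r2) {
        near = true;
        if (mt.state == 0)
          W.ngrow[i]++;
        else
          W.nshrink[i]++;
      }
    }
    if (mt.state == 1 && W.P.deposit_min_contact > 0) {
      // a retraction deposits while its filament keeps enough cortical
      // contact (a tip merely receding radially does not)
      mt.dep_armed = near &&
          membrane_contact_length(W, mt) >= W.P.deposit_min_contact;
      if (mt.dep_armed) {
        for (int i = 0; i < W.nm; i++) {
          double dx = tx - W.mx[i], dy = ty - W.my[i];
          if (dx * dx + dy * dy < r2) W.ndep[i]++;
        }
      }
    }
  }
  if (W.P.deposit_min_contact <= 0) W.ndep = W.nshrink;
}

// ---------------------------------------------------------------------------
// Dynein motors
// ---------------------------------------------------------------------------

static void motor_attach(World &W) {
  double p_on = 1.0 - std::exp(-W.P.k_on * W.P.dt);
  double rc2 = W.P.r_capture * W.P.r_capture;
  for (size_t q = 0; q < W.motors.size(); q++) {
    Motor &mo = W.motors[q];
    if (mo.bound) continue;
    double u = u01(W.rng_motor);
    if (u >= p_on) continue;
    double ax = mo.loop == 0 ? W.mx[mo.bead] : W.nx_[mo.bead];
    double ay = mo.loop == 0 ? W.my[mo.bead] : W.ny_[mo.bead];
    // nearest MT arc point within capture radius
    double best = rc2;
    int best_mt = -1;
    double best_arc = 0.0;
    for (size_t m = 0; m < W.mts.size(); m++) {
      MTchain &mt = W.mts[m];
      int nb = (int)mt.x.size();
      for (int k = 0; k + 1 < nb; k++) {
        double sx = mt.x[k], sy = mt.y[k];
        double dx = mt.x[k + 1] - sx, dy = mt.y[k + 1] - sy;
        double L2 = dx * dx + dy * dy;
        double tt = 0.0;
        if (L2 > 1e-24)
          tt = std::min(1.0, std::max(0.0, ((ax - sx) * dx + (ay - sy) * dy) / L2));
        double px = sx + tt * dx - ax, py = sy + tt * dy - ay;
        double d2 = px * px + py * py;
        if (d2 < best) {
          best = d2;
          best_mt = (int)m;
          best_arc = (k + tt) * W.P.sigma_mt;
        }
      }
      if (nb == 1) {
        double px = mt.x[0] - ax, py = mt.y[0] - ay;
        double d2 = px * px + py * py;
        if (d2 < best) {
          best = d2;
          best_mt = (int)m;
          best_arc = 0.0;
        }
      }
    }
    if (best_mt >= 0) {
      mo.bound = 1;
      mo.mt = best_mt;
      mo.arc = best_arc;
    }
  }
}

static void motor_step_and_pull(World &W) {
  double p_off = 1.0 - std::exp(-W.P.k_off * W.P.dt);
  for (size_t q = 0; q < W.motors.size(); q++) {
    Motor &mo = W.motors[q];
    if (!mo.bound) continue;
    MTchain &mt = W.mts[mo.mt];
    int nb = (int)mt.x.size();
    double len = (nb - 1) * W.P.sigma_mt + mt.partial;
    mo.arc -= W.P.v_motor * W.P.dt; // walk toward the minus end
    if (mo.arc < 0.0) mo.arc = 0.0;
    if (mo.arc > len) { // tip shrank past the motor
      mo.bound = 0;
      double u = u01(W.rng_motor); // keep the per-bound-motor draw cadence
      (void)u;
      continue;
    }
    double s = mo.arc / W.P.sigma_mt;
    int k = (int)s;
    if (k > nb - 1) k = nb - 1;
    double f = s - k;
    int k2 = k + 1 < nb ? k + 1 : k;
    if (k2 == k) f = 0.0;
    double pxx = (1.0 - f) * mt.x[k] + f * mt.x[k2];
    double pyy = (1.0 - f) * mt.y[k] + f * mt.y[k2];
    double ax = mo.loop == 0 ? W.mx[mo.bead] : W.nx_[mo.bead];
    double ay = mo.loop == 0 ? W.my[mo.bead] : W.ny_[mo.bead];
    double fx = W.P.k_motor * (pxx - ax); // force on anchor, toward MT point
    double fy = W.P.k_motor * (pyy - ay);
    double fmag = std::sqrt(fx * fx + fy * fy);
    if (fmag > W.P.f_stall) {
      mo.bound = 0;
      double u = u01(W.rng_motor);
      (void)u;
      continue;
    }
    if (mo.loop == 0) {
      W.fmx[mo.bead] += fx;
      W.fmy[mo.bead] += fy;
    } else {
      W.fnx[mo.bead] += fx;
      W.fny[mo.bead] += fy;
    }
    mt.fx[k] -= (1.0 - f) * fx;
    mt.fy[k] -= (1.0 - f) * fy;
    mt.fx[k2] -= f * fx;
    mt.fy[k2] -= f * fy;
    double u = u01(W.rng_motor);
    if (u < p_off) mo.bound = 0;
  }
}

// ---------------------------------------------------------------------------
// World <-> R state conversion
// ---------------------------------------------------------------------------

static World world_from_r(const List &state, const List &params,
                          const List &env) {
  World W;
  W.P = read_pars(params);
  W.E = read_env(env);
  NumericMatrix mem(as<NumericMatrix>(state["membrane"]));
  NumericMatrix nuc(as<NumericMatrix>(state["nucleus"]));
  W.nm = mem.nrow();
  W.nn = nuc.nrow();
  W.mx.assign(W.nm, 0.0);
  W.my.assign(W.nm, 0.0);
  for (int i = 0; i < W.nm; i++) {
    W.mx[i] = mem(i, 0);
    W.my[i] = mem(i, 1);
  }
  W.nx_.assign(W.nn, 0.0);
  W.ny_.assign(W.nn, 0.0);
  for (int i = 0; i < W.nn; i++) {
    W.nx_[i] = nuc(i, 0);
    W.ny_[i] = nuc(i, 1);
  }
  NumericVector cen(state["centrosome"]);
  W.cx = cen[0];
  W.cy = cen[1];
  List mts(state["mts"]);
  for (int m = 0; m < mts.size(); m++) {
    List mt(mts[m]);
    NumericMatrix b(as<NumericMatrix>(mt["beads"]));
    MTchain c;
    for (int k = 0; k < b.nrow(); k++) {
      c.x.push_back(b(k, 0));
      c.y.push_back(b(k, 1));
      c.fx.push_back(0.0);
      c.fy.push_back(0.0);
    }
    c.state = as<std::string>(mt["state"]) == "SHRINK" ? 1 : 0;
    c.partial = as<double>(mt["partial"]);
    c.dir = as<double>(mt["dir"]);
    c.stalled = false;
    c.dep_armed = mt.containsElementNamed("dep_armed") ?
        as<bool>(mt["dep_armed"]) : false;
    W.mts.push_back(c);
  }
  DataFrame mo(as<DataFrame>(state["motors"]));
  if (mo.nrows() > 0) {
    IntegerVector loop = mo["loop"], bead = mo["bead"], mtj = mo["mt"];
    LogicalVector bound = mo["bound"];
    NumericVector arc = mo["arc"];
    for (int i = 0; i < loop.size(); i++)
      W.motors.push_back({loop[i], bead[i] - 1, bound[i] ? 1 : 0,
                          mtj[i] == NA_INTEGER ? -1 : mtj[i] - 1, arc[i]});
  }
  W.t = as<double>(state["t"]);
  rng_load(W.rng_mt, as<std::string>(state["rng_mt"]));
  rng_load(W.rng_motor, as<std::string>(state["rng_motor"]));
  // fixed index-proportional nucleus -> membrane coupling map
  W.cmap.resize(W.nn);
  for (int j = 0; j < W.nn; j++)
    W.cmap[j] = (int)std::lround((double)j * W.nm / W.nn) % W.nm;
  W.fmx.assign(W.nm, 0.0);
  W.fmy.assign(W.nm, 0.0);
  W.fnx.assign(W.nn, 0.0);
  W.fny.assign(W.nn, 0.0);
  W.vmx.assign(W.nm, 0.0);
  W.vmy.assign(W.nm, 0.0);
  W.norx.assign(W.nm, 0.0);
  W.nory.assign(W.nm, 0.0);
  W.ngrow.assign(W.nm, 0);
  W.nshrink.assign(W.nm, 0);
  W.ndep.assign(W.nm, 0);
  W.ctrace.assign(W.nm, 0.0);
  if (state.containsElementNamed("contract_trace")) {
    NumericVector ct(state["contract_trace"]);
    if (ct.size() == W.nm)
      for (int i = 0; i < W.nm; i++) W.ctrace[i] = ct[i];
  }
  W.fcx = W.fcy = 0.0;
  W.overlaps = 0;
  W.max_internal_sum = 0.0;
  W.px_sum = W.py_sum = 0.0;
  return W;
}

static List world_to_r(World &W) {
  NumericMatrix mem(W.nm, 2), nuc(W.nn, 2);
  for (int i = 0; i < W.nm; i++) {
    mem(i, 0) = W.mx[i];
    mem(i, 1) = W.my[i];
  }
  for (int i = 0; i < W.nn; i++) {
    nuc(i, 0) = W.nx_[i];
    nuc(i, 1) = W.ny_[i];
  }
  List mts(W.mts.size());
  for (size_t m = 0; m < W.mts.size(); m++) {
    MTchain &c = W.mts[m];
    NumericMatrix b((int)c.x.size(), 2);
    for (int k = 0; k < (int)c.x.size(); k++) {
      b(k, 0) = c.x[k];
      b(k, 1) = c.y[k];
    }
    mts[m] = List::create(_["beads"] = b,
                          _["state"] = c.state == 1 ? "SHRINK" : "GROW",
                          _["partial"] = c.partial, _["dir"] = c.dir,
                          _["dep_armed"] = c.dep_armed);
  }
  int nmo = (int)W.motors.size();
  IntegerVector loop(nmo), bead(nmo), mtj(nmo);
  LogicalVector bound(nmo);
  NumericVector arc(nmo);
  for (int i = 0; i < nmo; i++) {
    loop[i] = W.motors[i].loop;
    bead[i] = W.motors[i].bead + 1;
    bound[i] = W.motors[i].bound == 1;
    mtj[i] = W.motors[i].mt >= 0 ? W.motors[i].mt + 1 : NA_INTEGER;
    arc[i] = W.motors[i].arc;
  }
  DataFrame mo = DataFrame::create(_["loop"] = loop, _["bead"] = bead,
                                   _["bound"] = bound, _["mt"] = mtj,
                                   _["arc"] = arc);
  return List::create(
      _["membrane"] = mem, _["nucleus"] = nuc,
      _["centrosome"] = NumericVector::create(W.cx, W.cy), _["mts"] = mts,
      _["motors"] = mo, _["contract_trace"] = NumericVector(W.ctrace.begin(),
                                                            W.ctrace.end()),
      _["t"] = W.t, _["rng_mt"] = rng_save(W.rng_mt),
      _["rng_motor"] = rng_save(W.rng_motor));
}

// ---------------------------------------------------------------------------
// One force evaluation + Euler step
// ---------------------------------------------------------------------------

static double elastic_energy(World &W) {
  double e = 0.0;
  std::vector<double> dummy_x(W.nm, 0.0), dummy_y(W.nm, 0.0);
  // reuse force accumulation with scratch arrays by saving/restoring is
  // wasteful; energy terms are recomputed directly instead
  int n = W.nm;
  for (int i = 0; i < n; i++) {
    int j = (i + 1) % n;
    double dx = W.mx[j] - W.mx[i], dy = W.my[j] - W.my[i];
    double r = std::sqrt(dx * dx + dy * dy);
    e += 0.5 * W.P.ks_mem * (r - W.P.rest_mem) * (r - W.P.rest_mem);
  }
  for (int i = 0; i < W.nn; i++) {
    int j = (i + 1) % W.nn;
    double dx = W.nx_[j] - W.nx_[i], dy = W.ny_[j] - W.ny_[i];
    double r = std::sqrt(dx * dx + dy * dy);
    e += 0.5 * W.P.ks_nuc * (r - W.P.rest_nuc) * (r - W.P.rest_nuc);
  }
  // bending via the same discrete form used by the forces
  std::vector<double> fx(W.nm, 0.0), fy(W.nm, 0.0);
  double eb = 0.0;
  bend_accum(W.mx, W.my, true, W.P.kappa_mem, W.P.ang_mem, W.P.rest_mem, fx,
             fy, &eb);
  std::vector<double> fxn(W.nn, 0.0), fyn(W.nn, 0.0);
  bend_accum(W.nx_, W.ny_, true, W.P.kappa_nuc, W.P.ang_nuc, W.P.rest_nuc, fxn,
             fyn, &eb);
  for (size_t m = 0; m < W.mts.size(); m++) {
    MTchain &c = W.mts[m];
    int nb = (int)c.x.size();
    for (int k = 0; k + 1 < nb; k++) {
      double dx = c.x[k + 1] - c.x[k], dy = c.y[k + 1] - c.y[k];
      double r = std::sqrt(dx * dx + dy * dy);
      e += 0.5 * W.P.ks_mt * (r - W.P.sigma_mt) * (r - W.P.sigma_mt);
    }
    std::vector<double> fxm(nb, 0.0), fym(nb, 0.0);
    bend_accum(c.x, c.y, false, W.P.kappa_mt, 0.0, W.P.sigma_mt, fxm, fym,
               &eb);
  }
  e += eb;
  {
    std::vector<double> fx2(W.nm, 0.0), fy2(W.nm, 0.0);
    area_accum(W.mx, W.my, W.P.k_area_mem, W.P.A0_mem, fx2, fy2, &e);
    std::vector<double> fx3(W.nn, 0.0), fy3(W.nn, 0.0);
    area_accum(W.nx_, W.ny_, W.P.k_area_nuc, W.P.A0_nuc, fx3, fy3, &e);
  }
  // coupling springs
  for (int j = 0; j < W.nn; j++) {
    int i = W.cmap[j];
    double dx = W.mx[i] - W.nx_[j], dy = W.my[i] - W.ny_[j];
    double r = std::sqrt(dx * dx + dy * dy);
    e += 0.5 * W.P.k_couple * (r - W.P.rest_couple) * (r - W.P.rest_couple);
  }
  // steric: recompute potential only (forces discarded into scratch world
  // copies would be expensive; here we walk pairs directly)
  // Pair potential accumulated through steric_pairs would double-apply
  // forces, so do a brute potential-only pass.
  std::vector<BeadRef> B;
  gather_beads(W, B);
  double rc = WCA_CUT * W.P.sigma_mt;
  // brute is acceptable: energy is only evaluated at record cadence
  for (int i = 0; i < (int)B.size(); i++) {
    for (int j = i + 1; j < (int)B.size(); j++) {
      if (!pair_ok(B[i].type, B[i].sub, B[j].type, B[j].sub, W.nm)) continue;
      double dx = B[i].x - B[j].x, dy = B[i].y - B[j].y;
      if (std::fabs(dx) >= rc || std::fabs(dy) >= rc) continue;
      double r2 = dx * dx + dy * dy;
      if (r2 >= rc * rc) continue;
      e += wca_pot(std::sqrt(r2), W.P.sigma_mt, W.P.eps_wca);
    }
    if (B[i].type == 3) continue;
    for (size_t o = 0; o < W.E.ox.size(); o++) {
      double dx = B[i].x - W.E.ox[o], dy = B[i].y - W.E.oy[o];
      double g = std::sqrt(dx * dx + dy * dy) - W.E.orad[o];
      if (g < rc)
        e += wca_pot(std::max(g, 0.05 * W.P.sigma_mt), W.P.sigma_mt,
                     W.P.eps_wca);
    }
    for (size_t w = 0; w < W.E.wx1.size(); w++) {
      double ux, uy;
      double d = seg_dist(B[i].x, B[i].y, W.E.wx1[w], W.E.wy1[w], W.E.wx2[w],
                          W.E.wy2[w], ux, uy);
      double g = d - W.E.wall_half;
      if (g < rc)
        e += wca_pot(std::max(g, 0.05 * W.P.sigma_mt), W.P.sigma_mt,
                     W.P.eps_wca);
    }
  }
  return e;
}

// Advances the world by one time step. Returns false on guard violation
// (message via Rcpp::stop happens in the caller loop for context).
static void engine_step(World &W, bool check_forces) {
  // 1. stochastic MT state switching and tip advance
  mt_dynamic_switch(W);
  mt_advance_tips(W);

  // 2. reset accumulators
  std::fill(W.fmx.begin(), W.fmx.end(), 0.0);
  std::fill(W.fmy.begin(), W.fmy.end(), 0.0);
  std::fill(W.fnx.begin(), W.fnx.end(), 0.0);
  std::fill(W.fny.begin(), W.fny.end(), 0.0);
  std::fill(W.vmx.begin(), W.vmx.end(), 0.0);
  std::fill(W.vmy.begin(), W.vmy.end(), 0.0);
  W.fcx = W.fcy = 0.0;
  for (size_t m = 0; m < W.mts.size(); m++) {
    std::fill(W.mts[m].fx.begin(), W.mts[m].fx.end(), 0.0);
    std::fill(W.mts[m].fy.begin(), W.mts[m].fy.end(), 0.0);
  }

  // 3. tip signal field (normals + counts) for this configuration
  membrane_normals(W);
  tip_signals(W);

  // 4. internal passive forces
  stretch_accum(W.mx, W.my, true, W.P.ks_mem, W.P.rest_mem, W.fmx, W.fmy,
                nullptr);
  bend_accum(W.mx, W.my, true, W.P.kappa_mem, W.P.ang_mem, W.P.rest_mem,
             W.fmx, W.fmy, nullptr);
  stretch_accum(W.nx_, W.ny_, true, W.P.ks_nuc, W.P.rest_nuc, W.fnx, W.fny,
                nullptr);
  bend_accum(W.nx_, W.ny_, true, W.P.kappa_nuc, W.P.ang_nuc, W.P.rest_nuc,
             W.fnx, W.fny, nullptr);
  area_accum(W.mx, W.my, W.P.k_area_mem, W.P.A0_mem, W.fmx, W.fmy, nullptr);
  area_accum(W.nx_, W.ny_, W.P.k_area_nuc, W.P.A0_nuc, W.fnx, W.fny, nullptr);
  for (size_t m = 0; m < W.mts.size(); m++) {
    MTchain &c = W.mts[m];
    stretch_accum(c.x, c.y, false, W.P.ks_mt, W.P.sigma_mt, c.fx, c.fy,
                  nullptr);
    bend_accum(c.x, c.y, false, W.P.kappa_mt, 0.0, W.P.sigma_mt, c.fx, c.fy,
               nullptr);
    // polymerization ratchet of a stalled growing tip: a force dipole on the
    // terminal bond pushes the tip into the obstacle and the body backward,
    // sustaining the buckling/gliding drive of blocked polymerization
    int nb = (int)c.x.size();
    if (c.stalled && nb >= 2 && W.P.f_poly > 0) {
      double tx = c.x[nb - 1] - c.x[nb - 2];
      double ty = c.y[nb - 1] - c.y[nb - 2];
      double tl = std::sqrt(tx * tx + ty * ty);
      if (tl > 1e-12) {
        tx /= tl; ty /= tl;
        c.fx[nb - 1] += W.P.f_poly * tx;
        c.fy[nb - 1] += W.P.f_poly * ty;
        c.fx[nb - 2] -= W.P.f_poly * tx;
        c.fy[nb - 2] -= W.P.f_poly * ty;
      }
    }
  }
  steric_pairs(W, true, nullptr);
  // nucleus-membrane elastic coupling
  for (int j = 0; j < W.nn; j++) {
    int i = W.cmap[j];
    double dx = W.mx[i] - W.nx_[j], dy = W.my[i] - W.ny_[j];
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < 1e-12) continue;
    double fm = W.P.k_couple * (r - W.P.rest_couple);
    double ux = dx / r, uy = dy / r;
    W.fmx[i] -= fm * ux;
    W.fmy[i] -= fm * uy;
    W.fnx[j] += fm * ux;
    W.fny[j] += fm * uy;
  }

  // 5. dynein motors (internal forces)
  motor_attach(W);
  motor_step_and_pull(W);

  if (check_forces) {
    // all contributions so far are internal and must sum to zero
    double sx = W.fcx, sy = W.fcy;
    for (int i = 0; i < W.nm; i++) {
      sx += W.fmx[i];
      sy += W.fmy[i];
    }
    for (int i = 0; i < W.nn; i++) {
      sx += W.fnx[i];
      sy += W.fny[i];
    }
    for (size_t m = 0; m < W.mts.size(); m++)
      for (size_t k = 0; k < W.mts[m].fx.size(); k++) {
        sx += W.mts[m].fx[k];
        sy += W.mts[m].fy[k];
      }
    double s = std::max(std::fabs(sx), std::fabs(sy));
    if (s > W.max_internal_sum) W.max_internal_sum = s;
  }

  // 6. external forces and active velocities
  boundary_forces(W, nullptr);
  W.px_sum = W.py_sum = 0.0;
  for (int i = 0; i < W.nm; i++) {
    // cortical response saturates at n_sat tips per bead
    double vp = W.P.v_prot0 * std::min((double)W.ngrow[i], W.P.n_sat);
    W.vmx[i] += vp * W.norx[i];
    W.vmy[i] += vp * W.nory[i];
    W.px_sum += vp * W.norx[i];
    W.py_sum += vp * W.nory[i];
    // contraction signal: either the instantaneous shrink-tip count
    // (contract_tau = 0) or a deposit-and-decay memory trace of the
    // cortical regions shrinking tips traverse
    double csig;
    if (W.P.contract_tau > 0) {
      W.ctrace[i] += W.P.dt * (W.P.contract_deposit * W.ndep[i] -
                               W.ctrace[i] / W.P.contract_tau);
      csig = W.ctrace[i];
    } else {
      csig = (double)W.nshrink[i];
    }
    double fc = W.P.f_contr0 * std::min(csig, W.P.n_sat_c);
    W.fmx[i] -= fc * W.norx[i];
    W.fmy[i] -= fc * W.nory[i];
    if (W.P.v_chemo > 0) {
      W.vmx[i] += W.P.v_chemo * W.E.chemo_dx;
      W.vmy[i] += W.P.v_chemo * W.E.chemo_dy;
    }
  }

  // 7. transmit MT minus-end forces to the centrosome, then Euler update
  for (size_t m = 0; m < W.mts.size(); m++) {
    W.fcx += W.mts[m].fx[0];
    W.fcy += W.mts[m].fy[0];
  }
  double dmax = 0.5 * W.P.sigma_mt;
  double dt = W.P.dt;
  double worst = 0.0;
  const char *worst_kind = "none";
  for (int i = 0; i < W.nm; i++) {
    double dx = dt * (W.fmx[i] / W.P.gamma_mem + W.vmx[i]);
    double dy = dt * (W.fmy[i] / W.P.gamma_mem + W.vmy[i]);
    double d = std::max(std::fabs(dx), std::fabs(dy));
    if (d > worst) { worst = d; worst_kind = "membrane"; }
    W.mx[i] += dx;
    W.my[i] += dy;
  }
  for (int i = 0; i < W.nn; i++) {
    double dx = dt * W.fnx[i] / W.P.gamma_nuc;
    double dy = dt * W.fny[i] / W.P.gamma_nuc;
    double d = std::max(std::fabs(dx), std::fabs(dy));
    if (d > worst) { worst = d; worst_kind = "nucleus"; }
    W.nx_[i] += dx;
    W.ny_[i] += dy;
  }
  {
    double dx = dt * W.fcx / W.P.gamma_cen;
    double dy = dt * W.fcy / W.P.gamma_cen;
    double d = std::max(std::fabs(dx), std::fabs(dy));
    if (d > worst) { worst = d; worst_kind = "centrosome"; }
    W.cx += dx;
    W.cy += dy;
  }
  for (size_t m = 0; m < W.mts.size(); m++) {
    MTchain &c = W.mts[m];
    for (size_t k = 1; k < c.x.size(); k++) {
      double dx = dt * c.fx[k] / W.P.gamma_mt;
      double dy = dt * c.fy[k] / W.P.gamma_mt;
      double d = std::max(std::fabs(dx), std::fabs(dy));
      if (d > worst) { worst = d; worst_kind = "MT"; }
      c.x[k] += dx;
      c.y[k] += dy;
    }
    // minus end re-pinned to the centrosome
    c.x[0] = W.cx;
    c.y[0] = W.cy;
  }
  if (worst > dmax) {
    // locate the worst membrane bead again for diagnostics
    int wi = -1; double wv = 0;
    for (int i = 0; i < W.nm; i++) {
      double d = std::max(std::fabs(W.fmx[i]), std::fabs(W.fmy[i]));
      if (d > wv) { wv = d; wi = i; }
    }
    if (wi >= 0) {
      Rcpp::Rcout << "guard-diag: worst mem bead " << wi << " F=(" << W.fmx[wi]
                  << "," << W.fmy[wi] << ") v_act=(" << W.vmx[wi] << ","
                  << W.vmy[wi] << ") ngrow=" << W.ngrow[wi] << " nshrink="
                  << W.nshrink[wi] << "\n";
      int near = 0;
      for (size_t m = 0; m < W.mts.size(); m++)
        for (size_t k = 0; k < W.mts[m].x.size(); k++) {
          double dx = W.mts[m].x[k] - W.mx[wi], dy = W.mts[m].y[k] - W.my[wi];
          if (dx * dx + dy * dy < 0.36) near++;
        }
      Rcpp::Rcout << "guard-diag: MT beads within 0.6 um: " << near << "\n";
    }
    stop("timestep too large: %s bead displacement %f um exceeds %f um at t = %f",
         worst_kind, worst, dmax, W.t);
  }
  W.t += dt;
}

// ---------------------------------------------------------------------------
// Exported: low-level kernels (unit-testable surfaces)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_stretch_forces(NumericMatrix pos, bool closed, double ks,
                                 double rest) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), fx(n, 0.0), fy(n, 0.0);
  for (int i = 0; i < n; i++) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
  }
  stretch_accum(x, y, closed, ks, rest, fx, fy, nullptr);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; i++) {
    out(i, 0) = fx[i];
    out(i, 1) = fy[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_bend_forces(NumericMatrix pos, bool closed, double kappa,
                              double rest_angle, double rest_bond) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), fx(n, 0.0), fy(n, 0.0);
  for (int i = 0; i < n; i++) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
  }
  bend_accum(x, y, closed, kappa, rest_angle, rest_bond, fx, fy, nullptr);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; i++) {
    out(i, 0) = fx[i];
    out(i, 1) = fy[i];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_bend_energy(NumericMatrix pos, bool closed, double kappa,
                       double rest_angle, double rest_bond) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), fx(n, 0.0), fy(n, 0.0);
  for (int i = 0; i < n; i++) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
  }
  double e = 0.0;
  bend_accum(x, y, closed, kappa, rest_angle, rest_bond, fx, fy, &e);
  return e;
}

// [[Rcpp::export]]
NumericVector cpp_wca_force(NumericVector r, double sigma, double eps) {
  int n = r.size();
  NumericVector out(n);
  long ov = 0;
  for (int i = 0; i < n; i++) out[i] = wca_fmag(r[i], sigma, eps, &ov);
  if (ov > 0) Rf_warning("%ld deep overlap(s): WCA force capped", ov);
  return out;
}

// [[Rcpp::export]]
List cpp_steric_forces(List state, List params, List env, bool use_grid) {
  World W = world_from_r(state, params, env);
  steric_pairs(W, use_grid, nullptr);
  boundary_forces(W, nullptr);
  NumericMatrix fm(W.nm, 2), fn(W.nn, 2);
  for (int i = 0; i < W.nm; i++) {
    fm(i, 0) = W.fmx[i];
    fm(i, 1) = W.fmy[i];
  }
  for (int i = 0; i < W.nn; i++) {
    fn(i, 0) = W.fnx[i];
    fn(i, 1) = W.fny[i];
  }
  List fmt(W.mts.size());
  for (size_t m = 0; m < W.mts.size(); m++) {
    NumericMatrix f((int)W.mts[m].fx.size(), 2);
    for (int k = 0; k < f.nrow(); k++) {
      f(k, 0) = W.mts[m].fx[k];
      f(k, 1) = W.mts[m].fy[k];
    }
    fmt[m] = f;
  }
  return List::create(_["membrane"] = fm, _["nucleus"] = fn, _["mts"] = fmt,
                      _["centrosome"] =
                          NumericVector::create(W.fcx, W.fcy),
                      _["overlaps"] = (double)W.overlaps);
}

// [[Rcpp::export]]
List cpp_tip_signals(NumericMatrix membrane, NumericMatrix tips,
                     IntegerVector tip_state, double r_signal) {
  int nm = membrane.nrow();
  std::vector<double> mx(nm), my(nm);
  for (int i = 0; i < nm; i++) {
    mx[i] = membrane(i, 0);
    my[i] = membrane(i, 1);
  }
  double sgn = polygon_area(mx, my) >= 0 ? 1.0 : -1.0;
  IntegerVector ngrow(nm), nshrink(nm);
  NumericMatrix normals(nm, 2);
  double r2 = r_signal * r_signal;
  for (int i = 0; i < nm; i++) {
    for (int j = 0; j < tips.nrow(); j++) {
      double dx = tips(j, 0) - mx[i], dy = tips(j, 1) - my[i];
      if (dx * dx + dy * dy < r2) {
        if (tip_state[j] == 0)
          ngrow[i]++;
        else
          nshrink[i]++;
      }
    }
    int ip = (i - 1 + nm) % nm, in = (i + 1) % nm;
    double tx = mx[in] - mx[ip], ty = my[in] - my[ip];
    double tl = std::sqrt(tx * tx + ty * ty);
    if (tl < 1e-12) {
      normals(i, 0) = normals((i - 1 + nm) % nm, 0);
      normals(i, 1) = normals((i - 1 + nm) % nm, 1);
    } else {
      normals(i, 0) = sgn * ty / tl;
      normals(i, 1) = sgn * -tx / tl;
    }
  }
  return List::create(_["n_grow"] = ngrow, _["n_shrink"] = nshrink,
                      _["normals"] = normals);
}

// [[Rcpp::export]]
List cpp_motor_forces(NumericVector anchor, NumericMatrix mt_beads, double arc,
                      double k_motor, double sigma_mt) {
  int nb = mt_beads.nrow();
  double s = arc / sigma_mt;
  int k = (int)s;
  if (k > nb - 1) k = nb - 1;
  double f = s - k;
  int k2 = k + 1 < nb ? k + 1 : k;
  if (k2 == k) f = 0.0;
  double pxx = (1.0 - f) * mt_beads(k, 0) + f * mt_beads(k2, 0);
  double pyy = (1.0 - f) * mt_beads(k, 1) + f * mt_beads(k2, 1);
  double fx = k_motor * (pxx - anchor[0]);
  double fy = k_motor * (pyy - anchor[1]);
  NumericMatrix fmt(nb, 2);
  fmt(k, 0) -= (1.0 - f) * fx;
  fmt(k, 1) -= (1.0 - f) * fy;
  fmt(k2, 0) -= f * fx;
  fmt(k2, 1) -= f * fy;
  return List::create(_["anchor"] = NumericVector::create(fx, fy),
                      _["mt"] = fmt);
}

// ---------------------------------------------------------------------------
// Exported: initialization randomness, free-MT process, simulation driver
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_init_random(int seed, int nmt, int n_mem, int n_nuc,
                     double rho_cortex, double rho_nuc) {
  std::mt19937_64 rinit, rmt, rmotor;
  {
    std::seed_seq s1{seed, 101};
    rinit.seed(s1);
    std::seed_seq s2{seed, 202};
    rmt.seed(s2);
    std::seed_seq s3{seed, 303};
    rmotor.seed(s3);
  }
  NumericVector dirs(nmt), partials(nmt);
  for (int i = 0; i < nmt; i++) dirs[i] = 2.0 * M_PI * u01(rinit);
  // staggered nucleation: random sub-bead accumulators desynchronize the
  // first bead additions across the filament population
  for (int i = 0; i < nmt; i++) partials[i] = 0.999 * u01(rinit);
  LogicalVector host_mem(n_mem), host_nuc(n_nuc);
  for (int i = 0; i < n_mem; i++) host_mem[i] = u01(rinit) < rho_cortex;
  for (int i = 0; i < n_nuc; i++) host_nuc[i] = u01(rinit) < rho_nuc;
  return List::create(_["dirs"] = dirs, _["partials"] = partials,
                      _["host_mem"] = host_mem,
                      _["host_nuc"] = host_nuc,
                      _["rng_mt"] = rng_save(rmt),
                      _["rng_motor"] = rng_save(rmotor));
}

// Free (unconstrained) single-filament two-state length process, run with the
// same per-step switching and tip bookkeeping as the full engine.
// Returns lengths sampled every `sample_every` seconds.
// [[Rcpp::export]]
NumericVector cpp_free_mt(double vg, double vs, double fc, double fr,
                          double dt, double t_max, double sigma_mt, int seed,
                          double sample_every) {
  std::mt19937_64 rng;
  std::seed_seq s{seed, 202};
  rng.seed(s);
  double p_cat = 1.0 - std::exp(-fc * dt);
  double p_res = 1.0 - std::exp(-fr * dt);
  long nsteps = (long)std::llround(t_max / dt);
  long stride = std::max(1L, (long)std::llround(sample_every / dt));
  int state = 0;
  long nbeads = 1;
  double partial = 0.0;
  std::vector<double> out;
  out.reserve(nsteps / stride + 1);
  for (long i = 0; i < nsteps; i++) {
    double u = u01(rng);
    if (state == 0) {
      if (u < p_cat) state = 1;
    } else {
      if (u < p_res) state = 0;
    }
    if (state == 0) {
      partial += vg * dt;
      while (partial >= sigma_mt) {
        nbeads++;
        partial -= sigma_mt;
      }
    } else {
      partial -= vs * dt;
      while (partial < 0.0) {
        if (nbeads >= 2) {
          nbeads--;
          partial += sigma_mt;
        } else {
          state = 0;
          partial = 0.0;
          u01(rng); // fresh nucleation direction draw (unused in 1D)
          break;
        }
      }
    }
    if ((i + 1) % stride == 0)
      out.push_back((nbeads - 1) * sigma_mt + partial);
  }
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_simulate(List state, List params, List env, List control) {
  World W = world_from_r(state, params, env);
  double t_total = as<double>(control["t_total"]);
  double record_every = as<double>(control["record_every"]);
  bool check_forces = as<bool>(control["check_forces"]);
  bool stop_on_entry = as<bool>(control["stop_on_entry"]);
  double entry_depth = as<double>(control["entry_depth"]);
  bool with_energy = as<bool>(control["with_energy"]);

  long nsteps = (long)std::llround(t_total / W.P.dt);
  long stride = std::max(1L, (long)std::llround(record_every / W.P.dt));
  int nchan = (int)W.E.chx.size();
  int ncol = 14 + nchan;
  long nframes = nsteps / stride + 1;
  NumericMatrix track(nframes, ncol);
  long fr = 0;

  // frame recorder
  auto record = [&](long row) {
    double cxm = 0, cym = 0;
    for (int i = 0; i < W.nm; i++) {
      cxm += W.mx[i];
      cym += W.my[i];
    }
    cxm /= W.nm;
    cym /= W.nm;
    double nxm = 0, nym = 0;
    for (int i = 0; i < W.nn; i++) {
      nxm += W.nx_[i];
      nym += W.ny_[i];
    }
    nxm /= W.nn;
    nym /= W.nn;
    double area = std::fabs(polygon_area(W.mx, W.my));
    // gyration tensor of membrane beads
    double sxx = 0, syy = 0, sxy = 0;
    for (int i = 0; i < W.nm; i++) {
      double dx = W.mx[i] - cxm, dy = W.my[i] - cym;
      sxx += dx * dx;
      syy += dy * dy;
      sxy += dx * dy;
    }
    sxx /= W.nm;
    syy /= W.nm;
    sxy /= W.nm;
    double tr = sxx + syy, det = sxx * syy - sxy * sxy;
    double disc = std::sqrt(std::max(0.0, tr * tr / 4.0 - det));
    double l1 = tr / 2.0 + disc, l2 = tr / 2.0 - disc;
    double aspect = (l2 > 1e-12) ? std::sqrt(l1 / l2) : NA_REAL;
    int ng = 0, ns = 0;
    for (size_t m = 0; m < W.mts.size(); m++) {
      if (W.mts[m].state == 0)
        ng++;
      else
        ns++;
    }
    track(row, 0) = W.t;
    track(row, 1) = cxm;
    track(row, 2) = cym;
    track(row, 3) = W.cx;
    track(row, 4) = W.cy;
    track(row, 5) = nxm;
    track(row, 6) = nym;
    track(row, 7) = area;
    track(row, 8) = aspect;
    track(row, 9) = ng;
    track(row, 10) = ns;
    track(row, 11) = W.px_sum;
    track(row, 12) = W.py_sum;
    track(row, 13) = with_energy ? elastic_energy(W) : NA_REAL;
    for (int c = 0; c < nchan; c++) {
      // minimum advance past the mouth, counted only while the whole cell
      // is laterally inside this lane (parallel channels share axes)
      double proj = std::numeric_limits<double>::infinity();
      double latmax = 0.0;
      for (int i = 0; i < W.nm; i++) {
        double rx = W.mx[i] - W.E.chx[c], ry = W.my[i] - W.E.chy[c];
        double p = rx * W.E.chdx[c] + ry * W.E.chdy[c];
        double lat = std::fabs(-rx * W.E.chdy[c] + ry * W.E.chdx[c]);
        proj = std::min(proj, p);
        latmax = std::max(latmax, lat);
      }
      if (latmax > W.E.chw[c] / 2.0 + 1.0) proj = -1e9;
      track(row, 14 + c) = proj;
    }
    // NaN guard at record cadence
    if (!std::isfinite(cxm) || !std::isfinite(W.cx) || !std::isfinite(area))
      stop("non-finite coordinates at t = %f (numerical blow-up)", W.t);
  };

  record(fr++);
  bool entered = false;
  for (long i = 0; i < nsteps; i++) {
    engine_step(W, check_forces);
    if ((i + 1) % stride == 0) {
      record(fr++);
      if (!containment_ok(W))
        stop("timestep too large: bead inside an obstacle or wall at t = %f",
             W.t);
      if (stop_on_entry && nchan > 0) {
        for (int c = 0; c < nchan; c++)
          if (track(fr - 1, 14 + c) >= entry_depth) entered = true;
        if (entered) break;
      }
      if ((fr % 50) == 0) Rcpp::checkUserInterrupt();
    }
  }
  NumericMatrix tr2 = track(Range(0, fr - 1), Range(0, ncol - 1));
  CharacterVector cn(ncol);
  const char *base[14] = {"t",  "x",  "y",      "cx",      "cy",
                          "nx", "ny", "area",   "aspect",  "n_grow",
                          "n_shrink", "px", "py", "energy"};
  for (int c = 0; c < 14; c++) cn[c] = base[c];
  for (int c = 0; c < nchan; c++)
    cn[14 + c] = std::string("chan_") + std::to_string(c + 1);
  colnames(tr2) = cn;
  return List::create(
      _["track"] = tr2, _["state"] = world_to_r(W),
      _["diag"] = List::create(_["max_internal_force_sum"] = W.max_internal_sum,
                               _["overlaps"] = (double)W.overlaps,
                               _["steps"] = (double)nsteps,
                               _["entered"] = entered));
}
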