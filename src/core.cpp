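// Numerical core: confinement wall geometry, bonded/WCA/lj93 force field with
// linked-cell + Verlet neighbour search, capped-force push-off relaxation, and
// the BAOAB Langevin integrator. All lengths in sigma, energies in epsilon,
// times in tau; kB = 1.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_set>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t v) {
  v += 0x9E3779B97F4A7C15ULL;
  v = (v ^ (v >> 30)) * 0xBF58476D1CE4E5B9ULL;
  v = (v ^ (v >> 27)) * 0x94D049BB133111EBULL;
  return v ^ (v >> 31);
}

static inline double u01(uint64_t k) {
  // strictly inside (0, 1)
  return ((splitmix64(k) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// ---------------------------------------------------------------- confinement

struct Conf {
  int kind;     // 1 cylinder, 2 spherocylinder, 3 compressed (cylinder∩slab)
  double R;     // lateral radius
  double halfL; // half axis length (kinds 1, 3)
  double halfC; // half cylindrical length (kind 2)
  double halfH; // half slab gap (kind 3)
};

static Conf parse_conf(const List& cl) {
  Conf c;
  std::string kind = as<std::string>(cl["kind"]);
  if (kind == "cylinder") {
    c.kind = 1;
    c.R = as<double>(cl["diameter"]) / 2.0;
    c.halfL = as<double>(cl["length"]) / 2.0;
    c.halfC = 0; c.halfH = 0;
  } else if (kind == "spherocylinder") {
    c.kind = 2;
    c.R = as<double>(cl["diameter"]) / 2.0;
    c.halfC = as<double>(cl["cyl_length"]) / 2.0;
    c.halfL = 0; c.halfH = 0;
  } else if (kind == "compressed") {
    c.kind = 3;
    c.R = as<double>(cl["width"]) / 2.0;
    c.halfH = as<double>(cl["height"]) / 2.0;
    c.halfL = as<double>(cl["length"]) / 2.0;
    c.halfC = 0;
  } else {
    stop("unknown confinement kind: " + kind);
  }
  return c;
}

// Fills gaps/normals for every wall element applicable at (x,y,z); returns the
// element count. Normals point from the wall into the interior; each element's
// gap strictly increases along its own normal. `lab` receives an element code:
// 0 lateral, 1 end plane z+, 2 end plane z-, 3 slab y+, 4 slab y-, 5 cap.
static int conf_walls(const Conf& c, double x, double y, double z,
                      double* g, double n[][3], int* lab) {
  int m = 0;
  if (c.kind == 1 || c.kind == 3) {
    double rho = std::sqrt(x * x + y * y);
    g[m] = c.R - rho;
    if (rho > 1e-12) { n[m][0] = -x / rho; n[m][1] = -y / rho; }
    else             { n[m][0] = 1.0;      n[m][1] = 0.0; }
    n[m][2] = 0.0; lab[m] = 0; m++;
    g[m] = c.halfL - z; n[m][0] = 0; n[m][1] = 0; n[m][2] = -1; lab[m] = 1; m++;
    g[m] = z + c.halfL; n[m][0] = 0; n[m][1] = 0; n[m][2] =  1; lab[m] = 2; m++;
    if (c.kind == 3) {
      g[m] = c.halfH - y; n[m][0] = 0; n[m][1] = -1; n[m][2] = 0; lab[m] = 3; m++;
      g[m] = y + c.halfH; n[m][0] = 0; n[m][1] =  1; n[m][2] = 0; lab[m] = 4; m++;
    }
  } else {
    // spherocylinder surface = points at distance R from the axis segment
    double zc = z;
    if (zc >  c.halfC) zc =  c.halfC;
    if (zc < -c.halfC) zc = -c.halfC;
    double dz = z - zc;
    double d = std::sqrt(x * x + y * y + dz * dz);
    g[m] = c.R - d;
    if (d > 1e-12) { n[m][0] = -x / d; n[m][1] = -y / d; n[m][2] = -dz / d; }
    else           { n[m][0] = 1.0;    n[m][1] = 0.0;    n[m][2] = 0.0; }
    lab[m] = (std::fabs(z) <= c.halfC) ? 0 : 5;
    m++;
  }
  return m;
}

static double conf_min_gap(const Conf& c, double x, double y, double z) {
  double g[5]; double n[5][3]; int lab[5];
  int m = conf_walls(c, x, y, z, g, n, lab);
  double mg = g[0];
  for (int k = 1; k < m; ++k) if (g[k] < mg) mg = g[k];
  return mg;
}

// [[Rcpp::export]]
List cpp_wall_contacts(NumericVector point, List conf) {
  Conf c = parse_conf(conf);
  double g[5]; double n[5][3]; int lab[5];
  int m = conf_walls(c, point[0], point[1], point[2], g, n, lab);
  NumericVector gap(m);
  NumericMatrix normal(m, 3);
  IntegerVector code(m);
  for (int k = 0; k < m; ++k) {
    gap[k] = g[k];
    for (int d = 0; d < 3; ++d) normal(k, d) = n[k][d];
    code[k] = lab[k];
  }
  return List::create(_["gap"] = gap, _["normal"] = normal, _["code"] = code);
}

// [[Rcpp::export]]
double cpp_min_gap(NumericVector point, List conf) {
  Conf c = parse_conf(conf);
  return conf_min_gap(c, point[0], point[1], point[2]);
}

// --------------------------------------------------------------- force field

struct FF {
  double eps, k_bond, r0, sigma, rp;
  double b_bb, b_bp;          // WCA contact distances
  double bw_bead, bw_part;    // wall contact distances
  double wall_cut_factor;     // cutoff = factor * b (2^(1/6) or (2/5)^(1/6))
  bool wall_shift;
  bool exclude_bonded;
  double skin;
};

static FF parse_ff(const List& p) {
  FF f;
  f.eps = as<double>(p["epsilon"]);
  f.k_bond = as<double>(p["k_bond"]);
  f.r0 = as<double>(p["r0"]);
  f.sigma = as<double>(p["sigma"]);
  f.rp = as<double>(p["particle_radius"]);
  f.b_bb = f.sigma;
  f.b_bp = 0.5 * f.sigma + f.rp;
  f.bw_bead = f.sigma;
  f.bw_part = 0.5 * f.sigma + f.rp;
  f.wall_cut_factor = as<double>(p["wall_cut_factor"]);
  f.wall_shift = as<bool>(p["wall_shift"]);
  f.exclude_bonded = as<bool>(p["exclude_bonded"]);
  f.skin = as<double>(p["skin"]);
  return f;
}

static inline uint64_t pair_key(int i, int j) {
  if (i > j) std::swap(i, j);
  return (static_cast<uint64_t>(i) << 32) | static_cast<uint32_t>(j);
}

// Linked-cell pair listing: all i<j pairs with r < rlist, minus exclusions.
static void build_pairs(const std::vector<double>& x, const std::vector<double>& y,
                        const std::vector<double>& z, double rlist,
                        const std::unordered_set<uint64_t>& excl,
                        std::vector<int>& pairs, bool use_cells) {
  int N = static_cast<int>(x.size());
  pairs.clear();
  double rl2 = rlist * rlist;
  if (!use_cells || N < 32) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        if (dx * dx + dy * dy + dz * dz < rl2 &&
            excl.find(pair_key(i, j)) == excl.end()) {
          pairs.push_back(i); pairs.push_back(j);
        }
      }
    return;
  }
  double lo[3] = {x[0], y[0], z[0]}, hi[3] = {x[0], y[0], z[0]};
  for (int i = 0; i < N; ++i) {
    lo[0] = std::min(lo[0], x[i]); hi[0] = std::max(hi[0], x[i]);
    lo[1] = std::min(lo[1], y[i]); hi[1] = std::max(hi[1], y[i]);
    lo[2] = std::min(lo[2], z[i]); hi[2] = std::max(hi[2], z[i]);
  }
  int nc[3];
  double inv[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] -= 1e-9; hi[d] += 1e-9;
    nc[d] = std::max(1, static_cast<int>(std::floor((hi[d] - lo[d]) / rlist)));
    inv[d] = nc[d] / (hi[d] - lo[d]);
  }
  int ncells = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncells, -1), nxt(N, -1), cell(N);
  for (int i = 0; i < N; ++i) {
    int cx = std::min(nc[0] - 1, static_cast<int>((x[i] - lo[0]) * inv[0]));
    int cy = std::min(nc[1] - 1, static_cast<int>((y[i] - lo[1]) * inv[1]));
    int cz = std::min(nc[2] - 1, static_cast<int>((z[i] - lo[2]) * inv[2]));
    int cc = (cz * nc[1] + cy) * nc[0] + cx;
    cell[i] = cc; nxt[i] = head[cc]; head[cc] = i;
  }
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int cc = (cz * nc[1] + cy) * nc[0] + cx;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ex = cx + dx, ey = cy + dy, ez = cz + dz;
              if (ex < 0 || ex >= nc[0] || ey < 0 || ey >= nc[1] ||
                  ez < 0 || ez >= nc[2]) continue;
              int ccn = (ez * nc[1] + ey) * nc[0] + ex;
              if (ccn < cc) continue;  // visit each cell pair once
              for (int i = head[cc]; i >= 0; i = nxt[i])
                for (int j = (ccn == cc ? nxt[i] : head[ccn]); j >= 0; j = nxt[j]) {
                  double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
                  if (ddx * ddx + ddy * ddy + ddz * ddz < rl2 &&
                      excl.find(pair_key(i, j)) == excl.end()) {
                    pairs.push_back(std::min(i, j)); pairs.push_back(std::max(i, j));
                  }
                }
            }
      }
}

// [[Rcpp::export]]
IntegerMatrix cpp_pair_list(NumericMatrix pos, double cutoff, bool use_cells,
                            IntegerMatrix exclude) {
  int N = pos.nrow();
  std::vector<double> x(N), y(N), z(N);
  for (int i = 0; i < N; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  std::unordered_set<uint64_t> excl;
  for (int b = 0; b < exclude.nrow(); ++b)
    excl.insert(pair_key(exclude(b, 0), exclude(b, 1)));
  std::vector<int> pairs;
  build_pairs(x, y, z, cutoff, excl, pairs, use_cells);
  int np = static_cast<int>(pairs.size() / 2);
  IntegerMatrix out(np, 2);
  for (int k = 0; k < np; ++k) { out(k, 0) = pairs[2 * k]; out(k, 1) = pairs[2 * k + 1]; }
  return out;
}

// lj93 wall energy and -dU/dgap for one contact.
static inline void lj93(double gap, double b, double eps, double cutf,
                        bool shift, double& u, double& fg) {
  double cut = cutf * b;
  if (gap > cut) { u = 0; fg = 0; return; }
  double s = b / gap;
  double s3 = s * s * s;
  double s9 = s3 * s3 * s3;
  u = eps * ((2.0 / 15.0) * s9 - s3);
  if (shift) {
    double sc = b / cut, sc3 = sc * sc * sc, sc9 = sc3 * sc3 * sc3;
    u -= eps * ((2.0 / 15.0) * sc9 - sc3);
  }
  // -dU/dgap = eps * ( (6/5) b^9/g^10 - 3 b^3/g^4 )
  fg = eps * ((6.0 / 5.0) * s9 / gap - 3.0 * s3 / gap);
}

struct EvalScratch {
  std::vector<int> pairs;
  std::unordered_set<uint64_t> excl;
};

// Core energy/force evaluation given a prebuilt pair list (built at >= max
// WCA cutoff). Returns potential energy; fills forces; tracks min wall gap.
static double eval_forces(const std::vector<double>& x, const std::vector<double>& y,
                          const std::vector<double>& z, const std::vector<int>& species,
                          const IntegerMatrix& bonds, const Conf& c, const FF& ff,
                          const std::vector<int>& pairs,
                          std::vector<double>& fx, std::vector<double>& fy,
                          std::vector<double>& fz, double& min_gap) {
  int N = static_cast<int>(x.size());
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double pe = 0.0;
  const double wca_fac2 = std::pow(2.0, 1.0 / 3.0);  // (2^(1/6))^2

  // bonds
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - ff.r0;
    pe += 0.5 * ff.k_bond * dr * dr;
    if (r > 1e-12) {
      double fr = -ff.k_bond * dr / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  }

  // WCA pairs
  int np = static_cast<int>(pairs.size() / 2);
  for (int k = 0; k < np; ++k) {
    int i = pairs[2 * k], j = pairs[2 * k + 1];
    double b = (species[i] + species[j] == 0) ? ff.b_bb : ff.b_bp;
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= wca_fac2 * b * b) continue;
    if (r2 < 1e-12) stop("overlapping beads in WCA evaluation");
    double sr2 = b * b / r2;
    double sr6 = sr2 * sr2 * sr2;
    pe += 4.0 * ff.eps * (sr6 * sr6 - sr6) + ff.eps;
    double fpair = 4.0 * ff.eps * (12.0 * sr6 * sr6 - 6.0 * sr6) / r2;
    fx[i] += fpair * dx; fy[i] += fpair * dy; fz[i] += fpair * dz;
    fx[j] -= fpair * dx; fy[j] -= fpair * dy; fz[j] -= fpair * dz;
  }

  // walls
  min_gap = std::numeric_limits<double>::infinity();
  double g[5]; double n[5][3]; int lab[5];
  for (int i = 0; i < N; ++i) {
    double bw = species[i] == 0 ? ff.bw_bead : ff.bw_part;
    int m = conf_walls(c, x[i], y[i], z[i], g, n, lab);
    for (int k = 0; k < m; ++k) {
      if (g[k] <= 0.0)
        stop("escaped-bead: bead %d outside confinement at (%g, %g, %g)",
             i + 1, x[i], y[i], z[i]);
      if (g[k] < min_gap) min_gap = g[k];
      double u, fg;
      lj93(g[k], bw, ff.eps, ff.wall_cut_factor, ff.wall_shift, u, fg);
      pe += u;
      fx[i] += fg * n[k][0]; fy[i] += fg * n[k][1]; fz[i] += fg * n[k][2];
    }
  }
  return pe;
}

static void fill_excl(const IntegerMatrix& bonds, bool exclude_bonded,
                      std::unordered_set<uint64_t>& excl) {
  excl.clear();
  if (!exclude_bonded) return;
  for (int b = 0; b < bonds.nrow(); ++b)
    excl.insert(pair_key(bonds(b, 0), bonds(b, 1)));
}

// [[Rcpp::export]]
List cpp_ff_eval(NumericMatrix pos, IntegerVector species, IntegerMatrix bonds,
                 List conf, List params, bool use_cells) {
  Conf c = parse_conf(conf);
  FF ff = parse_ff(params);
  int N = pos.nrow();
  std::vector<double> x(N), y(N), z(N), fx(N), fy(N), fz(N);
  std::vector<int> sp(N);
  bool has_part = false;
  for (int i = 0; i < N; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    sp[i] = species[i];
    if (sp[i] == 1) has_part = true;
  }
  double maxb = has_part ? std::max(ff.b_bb, ff.b_bp) : ff.b_bb;
  double rlist = std::pow(2.0, 1.0 / 6.0) * maxb;
  std::unordered_set<uint64_t> excl;
  fill_excl(bonds, ff.exclude_bonded, excl);
  std::vector<int> pairs;
  build_pairs(x, y, z, rlist, excl, pairs, use_cells);
  double min_gap;
  double pe = eval_forces(x, y, z, sp, bonds, c, ff, pairs, fx, fy, fz, min_gap);
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["energy"] = pe, _["forces"] = F, _["min_gap"] = min_gap,
                      _["n_pairs"] = static_cast<int>(pairs.size() / 2));
}

// ------------------------------------------------------- push-off relaxation

// Capped-force steepest descent on harmonic bonds + short-range soft pair
// repulsion + soft wall pushes. Resolves initial-configuration overlaps
// without the stiffness of the production potentials.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos, IntegerVector species, IntegerMatrix bonds,
               List conf, List params, int max_iter, double step_size,
               double dmax, double pair_tol, double wall_frac) {
  Conf c = parse_conf(conf);
  FF ff = parse_ff(params);
  int N = pos.nrow();
  std::vector<double> x(N), y(N), z(N), fx(N), fy(N), fz(N);
  std::vector<int> sp(N);
  bool has_part = false;
  for (int i = 0; i < N; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    sp[i] = species[i];
    if (sp[i] == 1) has_part = true;
  }
  double maxb = has_part ? std::max(ff.b_bb, ff.b_bp) : ff.b_bb;
  double rlist = maxb + 1.0;  // skin 1.0, rebuilt every 8 sweeps (dmax <= 0.06)
  std::unordered_set<uint64_t> excl;  // soft push applies to bonded pairs too? no:
  fill_excl(bonds, true, excl);       // bonds have their own term
  std::vector<int> pairs;
  std::vector<int> stuck(N, 0);
  // Bonds are softened and the push amplitude ramped over the schedule so
  // that overlap removal wins the force balance against bond pulls; the
  // production integrator restores exact bond statistics within ~gamma/k.
  const double k_soft = std::min(25.0, as<double>(params["k_bond"]));
  double worst_overlap = 0, worst_wall = 0, min_gap = 0;
  bool converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    double frac = static_cast<double>(it) / std::max(max_iter, 1);
    double A = 50.0 + 150.0 * (frac < 0.5 ? 2.0 * frac : 2.0 - 2.0 * frac);
    if (it % 8 == 0) build_pairs(x, y, z, rlist, excl, pairs, true);
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    std::fill(stuck.begin(), stuck.end(), 0);
    worst_overlap = 0.0;
    // bonds (pull toward r0)
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0), j = bonds(b, 1);
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-9) { dx = 1e-3 * ((i % 3) - 1); r = std::fabs(dx) + 1e-9; }
      double fr = -k_soft * (r - ff.r0) / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
    // soft pair push
    int np = static_cast<int>(pairs.size() / 2);
    for (int k = 0; k < np; ++k) {
      int i = pairs[2 * k], j = pairs[2 * k + 1];
      double b = (sp[i] + sp[j] == 0) ? ff.b_bb : ff.b_bp;
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= b * b) continue;
      double r = std::sqrt(r2);
      double ov = b - r;
      if (ov > worst_overlap) worst_overlap = ov;
      if (ov > pair_tol) { stuck[i] = 1; stuck[j] = 1; }
      double fr;
      if (r < 1e-9) { dx = 1e-3 * ((i % 3) - 1); r = std::fabs(dx) + 1e-9; fr = A / r; }
      else fr = A * (1.0 - r / b) / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
    // soft walls: push while gap below wall_frac * b_w (signed gap: also
    // recovers beads that start outside)
    min_gap = std::numeric_limits<double>::infinity();
    worst_wall = 0.0;
    double g[5]; double n[5][3]; int lab[5];
    for (int i = 0; i < N; ++i) {
      double bw = (sp[i] == 0 ? ff.bw_bead : ff.bw_part);
      double gtar = wall_frac * bw;
      int m = conf_walls(c, x[i], y[i], z[i], g, n, lab);
      for (int k = 0; k < m; ++k) {
        if (g[k] < min_gap) min_gap = g[k];
        if (g[k] < gtar) {
          double deficit = gtar - g[k];
          if (deficit > worst_wall) worst_wall = deficit;
          double fg = A * deficit / gtar;
          fx[i] += fg * n[k][0]; fy[i] += fg * n[k][1]; fz[i] += fg * n[k][2];
        }
      }
    }
    // wall tolerance 0.01 sigma below the target gap: lj93 forces there are
    // already O(1) and harmless to the integrator
    if (worst_overlap <= pair_tol && worst_wall <= 0.01) { converged = true; break; }
    // capped displacement
    for (int i = 0; i < N; ++i) {
      double dx = step_size * fx[i], dy = step_size * fy[i], dz = step_size * fz[i];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > dmax) { double s = dmax / d; dx *= s; dy *= s; dz *= s; }
      x[i] += dx; y[i] += dy; z[i] += dz;
    }
    // periodic deterministic kicks break descent limit cycles around
    // persistent deep overlaps
    if (it % 400 == 399) {
      for (int i = 0; i < N; ++i) {
        if (!stuck[i]) continue;
        uint64_t h = (static_cast<uint64_t>(it) * 2654435761ULL + i) * 3ULL;
        x[i] += 0.2 * (u01(h) - 0.5);
        y[i] += 0.2 * (u01(h + 1) - 0.5);
        z[i] += 0.2 * (u01(h + 2) - 0.5);
      }
    }
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
  return List::create(_["positions"] = out, _["iterations"] = it,
                      _["converged"] = converged,
                      _["worst_overlap"] = worst_overlap,
                      _["min_gap"] = min_gap);
}

// ------------------------------------------------------------- Langevin BAOAB

// Three standard normals for (seed stream s0, global step, bead i); draws are
// pure functions of their indices, so restarts reproduce the stream exactly.
static inline void gauss3(uint64_t s0, uint64_t step, uint64_t nbead, uint64_t i,
                          double& z0, double& z1, double& z2) {
  uint64_t base = (step * nbead + i) * 4ULL;
  double u1 = u01(s0 + base), u2 = u01(s0 + base + 1);
  double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
  z0 = r * std::cos(a);
  z1 = r * std::sin(a);
  double u3 = u01(s0 + base + 2), u4 = u01(s0 + base + 3);
  z2 = std::sqrt(-2.0 * std::log(u3)) * std::cos(6.283185307179586 * u4);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos0, NumericMatrix vel0, IntegerVector species,
             IntegerMatrix bonds, List conf, List params, NumericVector mass,
             double dt, double kBT, double gamma, double nsteps_d, double t0,
             double start_step_d, int seed, int dump_every, int thermo_every,
             IntegerVector tracked, bool collect) {
  Conf c = parse_conf(conf);
  FF ff = parse_ff(params);
  int N = pos0.nrow();
  int64_t nsteps = static_cast<int64_t>(nsteps_d);
  uint64_t gstep = static_cast<uint64_t>(start_step_d);
  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N), fx(N), fy(N), fz(N);
  std::vector<double> xr(N), yr(N), zr(N);  // positions at last pair build
  std::vector<int> sp(N);
  bool has_part = false;
  for (int i = 0; i < N; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
    sp[i] = species[i];
    if (sp[i] == 1) has_part = true;
  }
  double maxb = has_part ? std::max(ff.b_bb, ff.b_bp) : ff.b_bb;
  double rcut = std::pow(2.0, 1.0 / 6.0) * maxb;
  double rlist = rcut + ff.skin;
  double half_skin2 = 0.25 * ff.skin * ff.skin;
  std::unordered_set<uint64_t> excl;
  fill_excl(bonds, ff.exclude_bonded, excl);
  std::vector<int> pairs;

  uint64_t s0 = splitmix64(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                           0xD1B54A32D192ED03ULL);
  double c1 = std::exp(-gamma * dt);
  double cnoise = std::sqrt((1.0 - c1 * c1) * kBT);

  int ntr = tracked.size();
  int64_t nframes = collect && dump_every > 0 ? nsteps / dump_every + 1 : 0;
  NumericVector traj(nframes * static_cast<int64_t>(ntr) * 3);
  NumericVector frame_time(std::max<int64_t>(nframes, 0));
  std::vector<double> th_step, th_time, th_T, th_ke, th_pe, th_gap;

  auto rebuild = [&]() {
    build_pairs(x, y, z, rlist, excl, pairs, true);
    xr = x; yr = y; zr = z;
  };
  auto record_frame = [&](int64_t f, double tm) {
    frame_time[f] = tm;
    int64_t off = f * ntr * 3;
    for (int k = 0; k < ntr; ++k) {
      int i = tracked[k];
      traj[off + 3 * k] = x[i]; traj[off + 3 * k + 1] = y[i]; traj[off + 3 * k + 2] = z[i];
    }
  };
  auto kinetic = [&]() {
    double ke = 0;
    for (int i = 0; i < N; ++i)
      ke += 0.5 * mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return ke;
  };

  rebuild();
  double min_gap;
  double pe = eval_forces(x, y, z, sp, bonds, c, ff, pairs, fx, fy, fz, min_gap);
  int64_t f = 0;
  if (nframes > 0) record_frame(f++, t0);
  auto log_thermo = [&](int64_t s) {
    double ke = kinetic();
    th_step.push_back(static_cast<double>(gstep));
    th_time.push_back(t0 + s * dt);
    th_T.push_back(2.0 * ke / (3.0 * N));
    th_ke.push_back(ke);
    th_pe.push_back(pe);
    th_gap.push_back(min_gap);
  };
  if (thermo_every > 0) log_thermo(0);

  for (int64_t s = 0; s < nsteps; ++s) {
    for (int i = 0; i < N; ++i) {          // B
      double im = dt * 0.5 / mass[i];
      vx[i] += im * fx[i]; vy[i] += im * fy[i]; vz[i] += im * fz[i];
      x[i] += 0.5 * dt * vx[i];            // A
      y[i] += 0.5 * dt * vy[i];
      z[i] += 0.5 * dt * vz[i];
    }
    for (int i = 0; i < N; ++i) {          // O
      double z0, z1, z2;
      gauss3(s0, gstep, static_cast<uint64_t>(N), static_cast<uint64_t>(i), z0, z1, z2);
      double cn = cnoise / std::sqrt(mass[i]);
      vx[i] = c1 * vx[i] + cn * z0;
      vy[i] = c1 * vy[i] + cn * z1;
      vz[i] = c1 * vz[i] + cn * z2;
      x[i] += 0.5 * dt * vx[i];            // A
      y[i] += 0.5 * dt * vy[i];
      z[i] += 0.5 * dt * vz[i];
    }
    // Verlet-list validity check
    double dmax2 = 0;
    for (int i = 0; i < N; ++i) {
      double dx = x[i] - xr[i], dy = y[i] - yr[i], dz = z[i] - zr[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > dmax2) dmax2 = d2;
      if (!std::isfinite(x[i] + y[i] + z[i]))
        stop("integration blew up: non-finite coordinate for bead %d at step %g",
             i + 1, static_cast<double>(gstep));
    }
    if (dmax2 > half_skin2) rebuild();
    pe = eval_forces(x, y, z, sp, bonds, c, ff, pairs, fx, fy, fz, min_gap);
    for (int i = 0; i < N; ++i) {          // B
      double im = dt * 0.5 / mass[i];
      vx[i] += im * fx[i]; vy[i] += im * fy[i]; vz[i] += im * fz[i];
    }
    ++gstep;
    if (nframes > 0 && (s + 1) % dump_every == 0) record_frame(f++, t0 + (s + 1) * dt);
    if (thermo_every > 0 && (s + 1) % thermo_every == 0) log_thermo(s + 1);
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pout(N, 3), vout(N, 3);
  for (int i = 0; i < N; ++i) {
    pout(i, 0) = x[i]; pout(i, 1) = y[i]; pout(i, 2) = z[i];
    vout(i, 0) = vx[i]; vout(i, 1) = vy[i]; vout(i, 2) = vz[i];
  }
  traj.attr("dim") = IntegerVector::create(3, ntr, static_cast<int>(nframes));
  return List::create(
      _["positions"] = pout, _["velocities"] = vout,
      _["traj"] = traj, _["frame_time"] = frame_time,
      _["thermo"] = DataFrame::create(
          _["step"] = th_step, _["time"] = th_time, _["temperature"] = th_T,
          _["kinetic"] = th_ke, _["potential"] = th_pe, _["min_gap"] = th_gap),
      _["end_step"] = static_cast<double>(gstep), _["end_time"] = t0 + nsteps * dt);
}
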