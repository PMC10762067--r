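// Core molecular-dynamics kernels: truncated-shifted LJ pair forces over a
// 4-species interaction table, FENE / harmonic bonds, the patch-core-patch
// angle term, a Verlet neighbour list (all-pairs or cell-list build), a
// velocity-Verlet integrator with impulse-style Langevin thermostat, and a
// capped steepest-descent push-off used to relax freshly packed systems.
//
// Units: lengths in sigma, energies in epsilon = kT, times in tau; all
// masses are 1, so the friction coefficient is 1/damping_time.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>
#include <sstream>

using namespace Rcpp;

namespace {

// xoshiro256++ uniform generator (seeded via splitmix64) with a ziggurat
// normal sampler; the thermostat draws ~3N Gaussians per step, so this is
// performance-critical
struct FastRng {
  uint64_t s[4];
  explicit FastRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // in (0, 1]
    return ((next() >> 11) + 1) * 1.1102230246251565e-16;
  }
};

struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];
  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

inline double rnorm_zig(FastRng& rng, const Ziggurat& z) {
  for (;;) {
    int32_t hz = (int32_t)(uint32_t)rng.next();
    uint32_t iz = (uint32_t)hz & 127;
    uint32_t ahz = hz >= 0 ? (uint32_t)hz : (uint32_t)(-(int64_t)hz);
    if (ahz < z.kn[iz]) return hz * z.wn[iz];
    const double r = 3.442619855899;
    if (iz == 0) {  // tail
      double xx, yy;
      do {
        xx = -std::log(rng.unif()) / r;
        yy = -std::log(rng.unif());
      } while (yy + yy < xx * xx);
      return (hz > 0) ? r + xx : -r - xx;
    }
    double x = hz * z.wn[iz];
    if (z.fn[iz] + rng.unif() * (z.fn[iz - 1] - z.fn[iz]) <
        std::exp(-0.5 * x * x)) {
      return x;
    }
  }
}

struct PairCoef {
  // flattened 4x4 species table, index = si*4 + sj (0-based species)
  double c12[16], c6[16], rc2[16], shift[16], sig[16];
  double lcut2[16];  // per-pair neighbour-list cutoff^2 (rc + skin)^2
  bool act[16];
  double rmax;  // largest active cutoff

  void set_skin(double skin) {
    for (int p = 0; p < 16; ++p) {
      double rc = act[p] ? std::sqrt(rc2[p]) : 0.0;
      lcut2[p] = act[p] ? (rc + skin) * (rc + skin) : 0.0;
    }
  }

  // restrict rmax to species actually present, so e.g. a crowder-free
  // system does not pay for the large crowder-crowder cutoff
  void trim_rmax(const std::vector<int>& sp) {
    bool present[4] = {false, false, false, false};
    for (size_t i = 0; i < sp.size(); ++i) present[sp[i]] = true;
    rmax = 0.0;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        int p = i * 4 + j;
        if (present[i] && present[j] && act[p]) {
          double rc = std::sqrt(rc2[p]);
          if (rc > rmax) rmax = rc;
        }
      }
  }
};

struct Bond {
  int i, j;
  int style;    // 1 = FENE, 2 = harmonic
  double k, r0;
};

struct Angle { int a, c, b; };

struct Topology {
  std::vector<Bond> bonds;
  std::vector<Angle> angles;
  double kb_ang;  // angle stiffness, minimum at theta = pi
};

// minimum image for wrapped coordinates (|d| < L guaranteed)
inline double wrap_delta(double d, double L, double invL) {
  if (d > 0.5 * L) return d - L;
  if (d < -0.5 * L) return d + L;
  return d;
}

PairCoef make_pair_coef(const NumericMatrix& eps, const NumericMatrix& sig,
                        const NumericMatrix& rcut, const LogicalMatrix& act) {
  PairCoef pc;
  pc.rmax = 0.0;
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      int p = i * 4 + j;
      pc.act[p] = act(i, j);
      if (pc.act[p]) {
        double s = sig(i, j), e = eps(i, j), rc = rcut(i, j);
        double s3 = s * s * s, s6 = s3 * s3;
        pc.c12[p] = 4.0 * e * s6 * s6;
        pc.c6[p] = 4.0 * e * s6;
        pc.rc2[p] = rc * rc;
        pc.sig[p] = s;
        double ir2 = 1.0 / (rc * rc), ir6 = ir2 * ir2 * ir2;
        pc.shift[p] = pc.c12[p] * ir6 * ir6 - pc.c6[p] * ir6;
        if (rc > pc.rmax) pc.rmax = rc;
      } else {
        pc.c12[p] = pc.c6[p] = pc.rc2[p] = pc.shift[p] = pc.sig[p] = 0.0;
      }
    }
  }
  return pc;
}

Topology make_topology(const NumericMatrix& bonds, const IntegerMatrix& angles,
                       double kb_ang) {
  Topology tp;
  tp.kb_ang = kb_ang;
  for (int b = 0; b < bonds.nrow(); ++b) {
    Bond bd;
    bd.i = (int)bonds(b, 0) - 1;
    bd.j = (int)bonds(b, 1) - 1;
    bd.style = (int)bonds(b, 2);
    bd.k = bonds(b, 3);
    bd.r0 = bonds(b, 4);
    tp.bonds.push_back(bd);
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    Angle an;
    an.a = angles(a, 0) - 1;
    an.c = angles(a, 1) - 1;
    an.b = angles(a, 2) - 1;
    tp.angles.push_back(an);
  }
  return tp;
}

// ---- neighbour list -------------------------------------------------------

// pairs stored flat as (i, j, ptype) triples; only active species pairs
// within their own list cutoff (rc_ij + skin) are kept
// each list entry also stores the periodic image shift of the pair at
// build time; pairs in the list are far from L/2 apart, so the shift
// cannot change before the next rebuild and the force loop needs no
// min-image branches
void build_pairs_all(const std::vector<double>& x, const std::vector<int>& sp,
                     int n, double L, double invL,
                     const PairCoef& pc, std::vector<int>& pairs,
                     std::vector<double>& shifts) {
  pairs.clear();
  shifts.clear();
  for (int i = 0; i < n - 1; ++i) {
    double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
    int si = sp[i];
    for (int j = i + 1; j < n; ++j) {
      int p = si * 4 + sp[j];
      if (!pc.act[p]) continue;
      double rx = xi - x[3 * j], ry = yi - x[3 * j + 1], rz = zi - x[3 * j + 2];
      double dx = wrap_delta(rx, L, invL);
      double dy = wrap_delta(ry, L, invL);
      double dz = wrap_delta(rz, L, invL);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < pc.lcut2[p]) {
        pairs.push_back(i);
        pairs.push_back(j);
        pairs.push_back(p);
        shifts.push_back(rx - dx);
        shifts.push_back(ry - dy);
        shifts.push_back(rz - dz);
      }
    }
  }
}

void build_pairs_cell(const std::vector<double>& x, const std::vector<int>& sp,
                      int n, double L, double invL, double cut,
                      const PairCoef& pc, std::vector<int>& pairs,
                      std::vector<double>& shifts) {
  int m = (int)std::floor(L / cut);
  if (m < 3) {  // cell list degenerates; fall back
    build_pairs_all(x, sp, n, L, invL, pc, pairs, shifts);
    return;
  }
  if (m > 60) m = 60;  // cap the grid; cells only need to be >= cut
  double cellw = L / m;
  int ncell = m * m * m;
  // persistent workspace: the grid is cleared incrementally (only cells
  // used last time), which matters because rebuilds are frequent
  static std::vector<int> head, nxt, ca, cb, cc, used;
  if ((int)head.size() != ncell) {
    head.assign(ncell, -1);
    used.clear();
  }
  for (size_t u = 0; u < used.size(); ++u) head[used[u]] = -1;
  used.clear();
  if ((int)nxt.size() < n) {
    nxt.resize(n);
    ca.resize(n);
    cb.resize(n);
    cc.resize(n);
  }
  for (int i = 0; i < n; ++i) {
    double xi = x[3 * i] - L * std::floor(x[3 * i] * invL);
    double yi = x[3 * i + 1] - L * std::floor(x[3 * i + 1] * invL);
    double zi = x[3 * i + 2] - L * std::floor(x[3 * i + 2] * invL);
    int a = (int)(xi / cellw); if (a >= m) a = m - 1;
    int b = (int)(yi / cellw); if (b >= m) b = m - 1;
    int c = (int)(zi / cellw); if (c >= m) c = m - 1;
    ca[i] = a; cb[i] = b; cc[i] = c;
    int idx = (a * m + b) * m + c;
    if (head[idx] < 0) used.push_back(idx);
    nxt[i] = head[idx];
    head[idx] = i;
  }
  pairs.clear();
  shifts.clear();
  // particle-centric scan of the 27-cell neighbourhood, deduplicated by
  // index order; robust to strongly inhomogeneous systems (collapsed coil
  // in a large box)
  for (int i = 0; i < n; ++i) {
    int si = sp[i];
    double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
    for (int da = -1; da <= 1; ++da) {
      int a2 = ca[i] + da;
      if (a2 < 0) a2 += m; else if (a2 >= m) a2 -= m;
      for (int db = -1; db <= 1; ++db) {
        int b2 = cb[i] + db;
        if (b2 < 0) b2 += m; else if (b2 >= m) b2 -= m;
        int rowbase = (a2 * m + b2) * m;
        for (int dc = -1; dc <= 1; ++dc) {
          int c2 = cc[i] + dc;
          if (c2 < 0) c2 += m; else if (c2 >= m) c2 -= m;
          for (int j = head[rowbase + c2]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            int p = si * 4 + sp[j];
            if (!pc.act[p]) continue;
            double rx = xi - x[3 * j];
            double ry = yi - x[3 * j + 1];
            double rz = zi - x[3 * j + 2];
            double dx = wrap_delta(rx, L, invL);
            double dy = wrap_delta(ry, L, invL);
            double dz = wrap_delta(rz, L, invL);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < pc.lcut2[p]) {
              pairs.push_back(i);
              pairs.push_back(j);
              pairs.push_back(p);
              shifts.push_back(rx - dx);
              shifts.push_back(ry - dy);
              shifts.push_back(rz - dz);
            }
          }
        }
      }
    }
  }
}

// ---- forces ---------------------------------------------------------------

struct EnergyBreakdown { double pair, bond, angle; };

// soft = true caps the FENE near its divergence and the LJ overlap force;
// used only by the push-off relaxation
double add_forces(const std::vector<double>& x, int n, double L, double invL,
                  const PairCoef& pc, const Topology& tp,
                  const std::vector<int>& pairs,
                  const std::vector<double>& shifts, std::vector<double>& f,
                  EnergyBreakdown& eb, bool soft, bool need_energy = true) {
  std::fill(f.begin(), f.end(), 0.0);
  eb.pair = eb.bond = eb.angle = 0.0;
  const double fcap = 1e4;  // per-pair |dU/dr| cap in soft mode
  size_t np = pairs.size() / 3;
  for (size_t q = 0; q < np; ++q) {
    int i = pairs[3 * q], j = pairs[3 * q + 1], p = pairs[3 * q + 2];
    double dx = x[3 * i] - x[3 * j] - shifts[3 * q];
    double dy = x[3 * i + 1] - x[3 * j + 1] - shifts[3 * q + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2] - shifts[3 * q + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= pc.rc2[p]) continue;
    double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2, ir12 = ir6 * ir6;
    double fr = (12.0 * pc.c12[p] * ir12 - 6.0 * pc.c6[p] * ir6) * ir2;
    if (soft) {
      double r = std::sqrt(r2);
      if (std::fabs(fr) * r > fcap) fr = fcap / r * (fr > 0 ? 1.0 : -1.0);
    }
    if (need_energy) {
      double u = pc.c12[p] * ir12 - pc.c6[p] * ir6 - pc.shift[p];
      if (soft && u > 1e3) u = 1e3;
      eb.pair += u;
    }
    f[3 * i] += fr * dx;  f[3 * i + 1] += fr * dy;  f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx;  f[3 * j + 1] -= fr * dy;  f[3 * j + 2] -= fr * dz;
  }
  for (size_t b = 0; b < tp.bonds.size(); ++b) {
    const Bond& bd = tp.bonds[b];
    double dx = wrap_delta(x[3 * bd.i] - x[3 * bd.j], L, invL);
    double dy = wrap_delta(x[3 * bd.i + 1] - x[3 * bd.j + 1], L, invL);
    double dz = wrap_delta(x[3 * bd.i + 2] - x[3 * bd.j + 2], L, invL);
    double r2 = dx * dx + dy * dy + dz * dz;
    double fr;
    if (bd.style == 1) {  // FENE: U = -k r0^2/2 ln(1 - (r/r0)^2)
      double rr = r2 / (bd.r0 * bd.r0);
      if (rr >= 1.0) {
        if (soft) rr = 0.96;  // clamp near divergence during relaxation
        else {
          std::ostringstream msg;
          msg << "FENE bond overstretched (r >= " << bd.r0 << " sigma) between "
              << "particles " << (bd.i + 1) << " and " << (bd.j + 1)
              << "; the integration has become unstable";
          throw std::runtime_error(msg.str());
        }
      }
      fr = -bd.k / (1.0 - rr);  // force/r on i along +d
      if (need_energy)
        eb.bond += -0.5 * bd.k * bd.r0 * bd.r0 * std::log(1.0 - rr);
    } else {              // harmonic: U = k (r - r0)^2
      double r = std::sqrt(r2);
      fr = (r > 1e-12) ? -2.0 * bd.k * (r - bd.r0) / r : 0.0;
      if (need_energy) eb.bond += bd.k * (r - bd.r0) * (r - bd.r0);
    }
    f[3 * bd.i] += fr * dx;  f[3 * bd.i + 1] += fr * dy;  f[3 * bd.i + 2] += fr * dz;
    f[3 * bd.j] -= fr * dx;  f[3 * bd.j + 1] -= fr * dy;  f[3 * bd.j + 2] -= fr * dz;
  }
  for (size_t a = 0; a < tp.angles.size(); ++a) {
    const Angle& an = tp.angles[a];
    double d1x = wrap_delta(x[3 * an.a] - x[3 * an.c], L, invL);
    double d1y = wrap_delta(x[3 * an.a + 1] - x[3 * an.c + 1], L, invL);
    double d1z = wrap_delta(x[3 * an.a + 2] - x[3 * an.c + 2], L, invL);
    double d2x = wrap_delta(x[3 * an.b] - x[3 * an.c], L, invL);
    double d2y = wrap_delta(x[3 * an.b + 1] - x[3 * an.c + 1], L, invL);
    double d2z = wrap_delta(x[3 * an.b + 2] - x[3 * an.c + 2], L, invL);
    double r1 = std::sqrt(d1x * d1x + d1y * d1y + d1z * d1z);
    double r2 = std::sqrt(d2x * d2x + d2y * d2y + d2z * d2z);
    double cth = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    double th = std::acos(cth);
    double dth = th - M_PI;
    eb.angle += tp.kb_ang * dth * dth;
    double s = std::sqrt(1.0 - cth * cth);
    if (s < 1e-8) s = 1e-8;
    double acoef = -2.0 * tp.kb_ang * dth / s;  // = -dU/dcos(theta) * (-1) chain
    double c11 = acoef * cth / (r1 * r1);
    double c12c = -acoef / (r1 * r2);
    double c22 = acoef * cth / (r2 * r2);
    double fax = c11 * d1x + c12c * d2x;
    double fay = c11 * d1y + c12c * d2y;
    double faz = c11 * d1z + c12c * d2z;
    double fbx = c22 * d2x + c12c * d1x;
    double fby = c22 * d2y + c12c * d1y;
    double fbz = c22 * d2z + c12c * d1z;
    f[3 * an.a] += fax;  f[3 * an.a + 1] += fay;  f[3 * an.a + 2] += faz;
    f[3 * an.b] += fbx;  f[3 * an.b + 1] += fby;  f[3 * an.b + 2] += fbz;
    f[3 * an.c] -= fax + fbx;
    f[3 * an.c + 1] -= fay + fby;
    f[3 * an.c + 2] -= faz + fbz;
  }
  return eb.pair + eb.bond + eb.angle;
}

void copy_in(const NumericMatrix& pos, std::vector<double>& x, double L) {
  int n = pos.nrow();
  double invL = 1.0 / L;
  x.resize(3 * n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      double xi = pos(i, k);
      x[3 * i + k] = xi - L * std::floor(xi * invL);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, IntegerVector species, double box,
                        NumericMatrix eps, NumericMatrix sigma,
                        NumericMatrix rcut, LogicalMatrix active,
                        NumericMatrix bonds, IntegerMatrix angles,
                        double kb_angle, std::string method) {
  int n = pos.nrow();
  PairCoef pc = make_pair_coef(eps, sigma, rcut, active);
  Topology tp = make_topology(bonds, angles, kb_angle);
  std::vector<double> x;
  copy_in(pos, x, box);
  std::vector<int> sp(n);
  for (int i = 0; i < n; ++i) sp[i] = species[i] - 1;
  pc.trim_rmax(sp);
  double invL = 1.0 / box;
  std::vector<int> pairs;
  std::vector<double> shifts;
  pc.set_skin(0.0);
  if (method == "cell")
    build_pairs_cell(x, sp, n, box, invL, pc.rmax, pc, pairs, shifts);
  else
    build_pairs_all(x, sp, n, box, invL, pc, pairs, shifts);
  std::vector<double> f(3 * n);
  EnergyBreakdown eb;
  double epot =
      add_forces(x, n, box, invL, pc, tp, pairs, shifts, f, eb, false);
  NumericMatrix fm(n, 3);
  for (int i = 0; i < n; ++i) {
    fm(i, 0) = f[3 * i];
    fm(i, 1) = f[3 * i + 1];
    fm(i, 2) = f[3 * i + 2];
  }
  return List::create(_["forces"] = fm, _["energy"] = epot,
                      _["pair"] = eb.pair, _["bond"] = eb.bond,
                      _["angle"] = eb.angle);
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, IntegerMatrix images,
                IntegerVector species, double box, NumericMatrix eps,
                NumericMatrix sigma, NumericMatrix rcut, LogicalMatrix active,
                NumericMatrix bonds, IntegerMatrix angles, double kb_angle,
                double dt, double temperature, double damping, bool thermostat,
                double skin, int n_steps, int sample_every, int seed) {
  int n = pos.nrow();
  PairCoef pc = make_pair_coef(eps, sigma, rcut, active);
  Topology tp = make_topology(bonds, angles, kb_angle);
  std::vector<double> x, v(3 * n), f(3 * n);
  copy_in(pos, x, box);
  std::vector<long long> img(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      v[3 * i + k] = vel(i, k);
      img[3 * i + k] = images(i, k);
    }
  std::vector<int> sp(n);
  for (int i = 0; i < n; ++i) sp[i] = species[i] - 1;
  pc.trim_rmax(sp);
  double invL = 1.0 / box;

  pc.set_skin(skin);
  double list_cut = pc.rmax + skin;
  bool use_cell = (n > 150) && (box / list_cut >= 3.0);
  std::vector<int> pairs;
  std::vector<double> shifts;
  std::vector<double> xref(3 * n);
  // positions are wrapped only at rebuild time (images updated there);
  // between rebuilds they drift by less than the skin, so the stored pair
  // image shifts stay valid and the hot loops are branch-free
  auto rebuild = [&]() {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        double sft = std::floor(x[3 * i + k] * invL);
        if (sft != 0.0) {
          x[3 * i + k] -= sft * box;
          img[3 * i + k] += (long long)sft;
        }
      }
    if (use_cell)
      build_pairs_cell(x, sp, n, box, invL, list_cut, pc, pairs, shifts);
    else
      build_pairs_all(x, sp, n, box, invL, pc, pairs, shifts);
    xref = x;
  };
  double half_skin2 = 0.25 * skin * skin;

  FastRng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  static const Ziggurat zig;
  double gam = 1.0 / damping;
  double noise_sd = std::sqrt(2.0 * temperature * gam / dt);

  int n_samples = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericVector frames(n_samples > 0 ? (R_xlen_t)n_samples * n * 3 : 0);
  IntegerVector frame_img(n_samples > 0 ? (R_xlen_t)n_samples * n * 3 : 0);
  NumericVector times(n_samples), epots(n_samples), ekins(n_samples);
  int isamp = 0;

  EnergyBreakdown eb;
  long n_rebuilds = 0;
  rebuild();
  add_forces(x, n, box, invL, pc, tp, pairs, shifts, f, eb, false);
  if (thermostat) {
    for (int k = 0; k < 3 * n; ++k)
      f[k] += -gam * v[k] + noise_sd * rnorm_zig(rng, zig);
  }
  double tkin_sum = 0.0;
  long tkin_count = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < 3 * n; ++k) {
      v[k] += 0.5 * dt * f[k];
      x[k] += dt * v[k];
    }
    // neighbour-list staleness check (no wrapping between rebuilds)
    double maxd2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - xref[3 * i];
      double dy = x[3 * i + 1] - xref[3 * i + 1];
      double dz = x[3 * i + 2] - xref[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > maxd2) maxd2 = d2;
    }
    if (maxd2 > half_skin2) { rebuild(); ++n_rebuilds; }
    bool sampling = (sample_every > 0 && step % sample_every == 0);
    double epot = add_forces(x, n, box, invL, pc, tp, pairs, shifts, f, eb,
                             false, sampling);
    if (thermostat) {
      for (int k = 0; k < 3 * n; ++k)
        f[k] += -gam * v[k] + noise_sd * rnorm_zig(rng, zig);
    }
    for (int k = 0; k < 3 * n; ++k) v[k] += 0.5 * dt * f[k];
    double v2 = 0.0;
    for (int k = 0; k < 3 * n; ++k) v2 += v[k] * v[k];
    tkin_sum += v2 / (3.0 * n);
    ++tkin_count;
    if (sampling) {
      if (!std::isfinite(x[0]) || !std::isfinite(epot)) {
        std::ostringstream msg;
        msg << "non-finite coordinates at step " << step
            << " (potential energy " << epot << "); reduce dt or check overlaps";
        throw std::runtime_error(msg.str());
      }
      R_xlen_t base = (R_xlen_t)isamp;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          double xi = x[3 * i + k];
          double sft = std::floor(xi * invL);
          // column-major [n_samples, n, 3]
          frames[base + (R_xlen_t)n_samples * (i + (R_xlen_t)n * k)] =
              xi - sft * box;
          frame_img[base + (R_xlen_t)n_samples * (i + (R_xlen_t)n * k)] =
              (int)(img[3 * i + k] + (long long)sft);
        }
      times[isamp] = step * dt;
      epots[isamp] = epot;
      ekins[isamp] = 0.5 * v2;
      ++isamp;
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  IntegerMatrix img_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double xi = x[3 * i + k];
      double sft = std::floor(xi * invL);
      pos_out(i, k) = xi - sft * box;
      vel_out(i, k) = v[3 * i + k];
      img_out(i, k) = (int)(img[3 * i + k] + (long long)sft);
    }
  if (n_samples > 0) {
    frames.attr("dim") = IntegerVector::create(n_samples, n, 3);
    frame_img.attr("dim") = IntegerVector::create(n_samples, n, 3);
  }
  return List::create(
      _["frames"] = frames, _["frame_images"] = frame_img, _["times"] = times,
      _["epot"] = epots, _["ekin"] = ekins, _["positions"] = pos_out,
      _["velocities"] = vel_out,
      _["images"] = img_out,
      _["mean_kinetic_temperature"] =
          tkin_count > 0 ? tkin_sum / tkin_count : NA_REAL,
      _["n_rebuilds"] = (double)n_rebuilds,
      _["n_pairs"] = (double)(pairs.size() / 3));
}

// [[Rcpp::export]]
List cpp_pushoff(NumericMatrix pos, IntegerVector species, double box,
                 NumericMatrix eps, NumericMatrix sigma, NumericMatrix rcut,
                 LogicalMatrix active, NumericMatrix bonds,
                 IntegerMatrix angles, double kb_angle, double gap_frac,
                 int max_iter, double max_disp) {
  int n = pos.nrow();
  PairCoef pc = make_pair_coef(eps, sigma, rcut, active);
  Topology tp = make_topology(bonds, angles, kb_angle);
  std::vector<double> x, f(3 * n);
  copy_in(pos, x, box);
  std::vector<int> sp(n);
  for (int i = 0; i < n; ++i) sp[i] = species[i] - 1;
  pc.trim_rmax(sp);
  double invL = 1.0 / box;
  std::vector<int> pairs;
  std::vector<double> shifts;
  pc.set_skin(0.3);
  double list_cut = pc.rmax + 0.3;
  bool use_cell = (n > 400) && (box / list_cut >= 4.0);
  EnergyBreakdown eb;

  auto min_gap = [&]() {
    double g = R_PosInf;
    size_t np = pairs.size() / 3;
    for (size_t q = 0; q < np; ++q) {
      int i = pairs[3 * q], j = pairs[3 * q + 1], p = pairs[3 * q + 2];
      if (pc.sig[p] <= 0) continue;
      double dx = wrap_delta(x[3 * i] - x[3 * j], box, invL);
      double dy = wrap_delta(x[3 * i + 1] - x[3 * j + 1], box, invL);
      double dz = wrap_delta(x[3 * i + 2] - x[3 * j + 2], box, invL);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ratio = r / pc.sig[p];
      if (ratio < g) g = ratio;
    }
    return g;
  };

  int it = 0;
  double g = 0.0;
  for (; it < max_iter; ++it) {
    if (use_cell)
      build_pairs_cell(x, sp, n, box, invL, list_cut, pc, pairs, shifts);
    else
      build_pairs_all(x, sp, n, box, invL, pc, pairs, shifts);
    g = min_gap();
    if (g >= gap_frac) break;
    add_forces(x, n, box, invL, pc, tp, pairs, shifts, f, eb, true);
    for (int i = 0; i < n; ++i) {
      double fx = f[3 * i], fy = f[3 * i + 1], fz = f[3 * i + 2];
      double fm = std::sqrt(fx * fx + fy * fy + fz * fz);
      if (fm < 1e-12) continue;
      double scale = 2e-4;  // descent step on capped forces
      double d = fm * scale;
      if (d > max_disp) scale = max_disp / fm;
      x[3 * i] += fx * scale;
      x[3 * i + 1] += fy * scale;
      x[3 * i + 2] += fz * scale;
    }
    for (int k = 0; k < 3 * n; ++k) x[k] -= box * std::floor(x[k] * invL);
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  return List::create(_["positions"] = out, _["min_gap_ratio"] = g,
                      _["iterations"] = it, _["converged"] = g >= gap_frac);
}
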