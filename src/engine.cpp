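// Coarse-grained HPS engine: Ashbaugh-Hatch + Debye-Hueckel pair
// interactions with harmonic bonds, cell-binned Verlet neighbor lists, a
// BAOAB Langevin integrator and a clamped steepest-descent minimizer.
// Units: A, kJ/mol, g/mol, ps.  Charges in elementary charges.  All
// periodic distances use the orthorhombic minimum image.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <sstream>
using namespace Rcpp;

// g/mol * (A/ps)^2 -> kJ/mol
static const double MV2_TO_KJ = 0.01;
static const double KB = 8.314462618e-3; // kJ/(mol K)

// ---------------------------------------------------------------- RNG -----
// Deterministic splitmix64-seeded xoshiro256++ with Box-Muller normals.
struct Rng {
  uint64_t s[4];
  bool has_cached = false;
  double cached = 0.0;
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double gauss() {
    if (has_cached) { has_cached = false; return cached; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u)), a = 2.0 * M_PI * v;
    cached = r * std::sin(a); has_cached = true;
    return r * std::cos(a);
  }
};

// ------------------------------------------------------------- system -----
struct FF {
  std::vector<double> sigma, lambda, q, mass; // per bead type
  double eps, bond_k, bond_r0, kappa, kq;     // kq = Coulomb prefactor / D
  double cut_vdw, cut_elec, cut_max;
};

static FF unpack_ff(const List& ffp) {
  FF ff;
  ff.sigma  = as<std::vector<double>>(ffp["sigma"]);
  ff.lambda = as<std::vector<double>>(ffp["lambda"]);
  ff.q      = as<std::vector<double>>(ffp["charge"]);
  ff.mass   = as<std::vector<double>>(ffp["mass"]);
  ff.eps = as<double>(ffp["epsilon"]);
  ff.bond_k = as<double>(ffp["bond_k"]);
  ff.bond_r0 = as<double>(ffp["bond_r0"]);
  ff.kappa = as<double>(ffp["debye_length"]);
  ff.kq = as<double>(ffp["kq"]);
  ff.cut_vdw = as<double>(ffp["cutoff_vdw"]);
  ff.cut_elec = as<double>(ffp["cutoff_elec"]);
  ff.cut_max = std::max(ff.cut_vdw, ff.cut_elec);
  return ff;
}

struct Sys {
  int n;
  std::vector<double> x, y, z;
  double bx, by, bz;
  std::vector<int> type;                  // 0-based
  std::vector<int> bondA, bondB;          // 0-based
  std::vector<std::vector<int>> bonded;   // exclusion partners per bead
};

static Sys unpack_sys(const NumericMatrix& pos, const NumericVector& box,
                      const IntegerVector& type, const IntegerMatrix& bonds) {
  Sys s;
  s.n = pos.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  s.bx = box[0]; s.by = box[1]; s.bz = box[2];
  s.type.assign(type.begin(), type.end());
  s.bonded.resize(s.n);
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    s.bondA.push_back(i); s.bondB.push_back(j);
    s.bonded[i].push_back(j); s.bonded[j].push_back(i);
  }
  return s;
}

// round-to-nearest via the 2^52 * 1.5 magic constant (no SSE4 roundsd on
// older x86 targets, where std::nearbyint is a libm call in the hot loop)
static inline double rnd_nearest(double x) {
  const double C = 6755399441055744.0;  // 1.5 * 2^52
  double y = x + C;
  y -= C;
  return y;
}

static inline double mind(double d, double L) {
  return d - L * rnd_nearest(d / L);
}

static inline double mindi(double d, double L, double iL) {
  return d - L * rnd_nearest(d * iL);
}

static inline bool excluded(const Sys& s, int i, int j) {
  for (int k : s.bonded[i]) if (k == j) return true;
  return false;
}

// ------------------------------------------------------- neighbor list ----
// Pairs (i < j) with minimum-image distance < rlist.  Cells are at least
// rlist wide, so all qualifying pairs sit in the same or adjacent cells;
// with fewer than three cells per dimension the wrapped 27-stencil is
// deduplicated, so each cell pair is visited exactly once.
struct PairList { std::vector<int> a, b; };

static void build_pairs(const Sys& s, double rlist, PairList& pl) {
  pl.a.clear(); pl.b.clear();
  double r2 = rlist * rlist;
  if (s.n < 64) {
    for (int i = 0; i < s.n; ++i)
      for (int j = i + 1; j < s.n; ++j) {
        double dx = mind(s.x[i] - s.x[j], s.bx);
        double dy = mind(s.y[i] - s.y[j], s.by);
        double dz = mind(s.z[i] - s.z[j], s.bz);
        if (dx * dx + dy * dy + dz * dz < r2) {
          pl.a.push_back(i); pl.b.push_back(j);
        }
      }
    return;
  }
  int ncx = std::max(1, (int)std::floor(s.bx / rlist));
  int ncy = std::max(1, (int)std::floor(s.by / rlist));
  int ncz = std::max(1, (int)std::floor(s.bz / rlist));
  int ncell = ncx * ncy * ncz;
  std::vector<int> head(ncell, -1), nxt(s.n, -1);
  auto wrapc = [](double u, double L, int nc) {
    double f = u / L - std::floor(u / L);
    int c = (int)(f * nc);
    return std::min(nc - 1, c);
  };
  for (int i = 0; i < s.n; ++i) {
    int c = (wrapc(s.z[i], s.bz, ncz) * ncy + wrapc(s.y[i], s.by, ncy)) * ncx +
            wrapc(s.x[i], s.bx, ncx);
    nxt[i] = head[c]; head[c] = i;
  }
  // per-cell deduplicated neighbor cells (only ids >= own id kept)
  std::vector<int> nb;
  nb.reserve(27);
  pl.a.reserve(s.n * 64); pl.b.reserve(s.n * 64);
  for (int cz = 0; cz < ncz; ++cz)
    for (int cy = 0; cy < ncy; ++cy)
      for (int cx = 0; cx < ncx; ++cx) {
        int c = (cz * ncy + cy) * ncx + cx;
        if (head[c] < 0) continue;
        nb.clear();
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int nx = (cx + dx + ncx) % ncx;
              int ny = (cy + dy + ncy) % ncy;
              int nz = (cz + dz + ncz) % ncz;
              int c2 = (nz * ncy + ny) * ncx + nx;
              if (c2 >= c) nb.push_back(c2);
            }
        std::sort(nb.begin(), nb.end());
        nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
        for (int c2 : nb) {
          for (int i = head[c]; i >= 0; i = nxt[i])
            for (int j = head[c2]; j >= 0; j = nxt[j]) {
              if (c2 == c && j >= i) continue;
              double dx = mind(s.x[i] - s.x[j], s.bx);
              double dy = mind(s.y[i] - s.y[j], s.by);
              double dz = mind(s.z[i] - s.z[j], s.bz);
              if (dx * dx + dy * dy + dz * dz < r2) {
                pl.a.push_back(std::min(i, j));
                pl.b.push_back(std::max(i, j));
              }
            }
        }
      }
}

// --------------------------------------------------- energies & forces ----
struct Energy { double bond = 0, vdw = 0, elec = 0; };

// Tabulated exp(-r/kappa)/r on r in (0, cut_elec], linear interpolation.
struct ElecTable {
  double dr, inv_dr, cut;
  std::vector<double> v;
  void init(double kappa, double cut_elec) {
    cut = cut_elec;
    int npts = 8192;
    dr = cut_elec / (npts - 1); inv_dr = 1.0 / dr;
    v.resize(npts);
    v[0] = 0.0;
    for (int i = 1; i < npts; ++i) {
      double r = i * dr;
      v[i] = std::exp(-r / kappa) / r;
    }
  }
  inline double eval(double r) const {
    double u = r * inv_dr;
    int i = (int)u;
    if (i >= (int)v.size() - 1) return v.back();
    double f = u - i;
    return v[i] * (1.0 - f) + v[i + 1] * f;
  }
};

static Energy eval(const Sys& s, const FF& ff, const PairList& pl,
                   const ElecTable* et,
                   std::vector<double>* fx, std::vector<double>* fy,
                   std::vector<double>* fz) {
  Energy e;
  bool wantf = fx != nullptr;
  if (wantf) {
    std::fill(fx->begin(), fx->end(), 0.0);
    std::fill(fy->begin(), fy->end(), 0.0);
    std::fill(fz->begin(), fz->end(), 0.0);
  }
  double c2v = ff.cut_vdw * ff.cut_vdw, c2e = ff.cut_elec * ff.cut_elec;
  double sixth2 = std::pow(2.0, 1.0 / 3.0); // (2^(1/6))^2
  double inv_kappa = 1.0 / ff.kappa;
  size_t np = pl.a.size();
  for (size_t p = 0; p < np; ++p) {
    int i = pl.a[p], j = pl.b[p];
    double dx = mind(s.x[i] - s.x[j], s.bx);
    double dy = mind(s.y[i] - s.y[j], s.by);
    double dz = mind(s.z[i] - s.z[j], s.bz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= c2v && r2 >= c2e) continue;
    if (excluded(s, i, j)) continue;
    double f_over_r = 0.0;
    int ti = s.type[i], tj = s.type[j];
    if (r2 < c2v) {
      double sig = 0.5 * (ff.sigma[ti] + ff.sigma[tj]);
      double lam = 0.5 * (ff.lambda[ti] + ff.lambda[tj]);
      double sr2 = sig * sig / r2;
      double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
      double lj = 4.0 * ff.eps * (sr12 - sr6);
      double flj = 24.0 * ff.eps * (2.0 * sr12 - sr6) / r2; // (-dU/dr)/r
      if (r2 <= sixth2 * sig * sig) {
        e.vdw += lj + (1.0 - lam) * ff.eps;
        f_over_r += flj;
      } else {
        e.vdw += lam * lj;
        f_over_r += lam * flj;
      }
    }
    double qq = ff.q[ti] * ff.q[tj];
    if (qq != 0.0 && r2 < c2e) {
      double r = std::sqrt(r2);
      double g = et ? et->eval(r) : std::exp(-r * inv_kappa) / r; // exp(-r/k)/r
      double u = ff.kq * qq * g;
      e.elec += u;
      f_over_r += u * (1.0 / r + inv_kappa) / r;
    }
    if (wantf && f_over_r != 0.0) {
      (*fx)[i] += f_over_r * dx; (*fx)[j] -= f_over_r * dx;
      (*fy)[i] += f_over_r * dy; (*fy)[j] -= f_over_r * dy;
      (*fz)[i] += f_over_r * dz; (*fz)[j] -= f_over_r * dz;
    }
  }
  for (size_t b = 0; b < s.bondA.size(); ++b) {
    int i = s.bondA[b], j = s.bondB[b];
    double dx = mind(s.x[i] - s.x[j], s.bx);
    double dy = mind(s.y[i] - s.y[j], s.by);
    double dz = mind(s.z[i] - s.z[j], s.bz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - ff.bond_r0;
    e.bond += 0.5 * ff.bond_k * d * d;
    if (wantf) {
      double f_over_r = -ff.bond_k * d / r;
      (*fx)[i] += f_over_r * dx; (*fx)[j] -= f_over_r * dx;
      (*fy)[i] += f_over_r * dy; (*fy)[j] -= f_over_r * dy;
      (*fz)[i] += f_over_r * dz; (*fz)[j] -= f_over_r * dz;
    }
  }
  return e;
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix pos, NumericVector box, IntegerVector type,
                IntegerMatrix bonds, List ffp, bool use_neighbor_list) {
  Sys s = unpack_sys(pos, box, type, bonds);
  FF ff = unpack_ff(ffp);
  PairList pl;
  if (use_neighbor_list) {
    build_pairs(s, ff.cut_max, pl);
  } else {
    for (int i = 0; i < s.n; ++i)
      for (int j = i + 1; j < s.n; ++j) { pl.a.push_back(i); pl.b.push_back(j); }
  }
  Energy e = eval(s, ff, pl, nullptr, nullptr, nullptr, nullptr);
  return List::create(_["bond"] = e.bond, _["vdw"] = e.vdw,
                      _["elec"] = e.elec,
                      _["total"] = e.bond + e.vdw + e.elec);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, NumericVector box,
                         IntegerVector type, IntegerMatrix bonds, List ffp) {
  Sys s = unpack_sys(pos, box, type, bonds);
  FF ff = unpack_ff(ffp);
  PairList pl;
  build_pairs(s, ff.cut_max, pl);
  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  eval(s, ff, pl, nullptr, &fx, &fy, &fz);
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return out;
}

// ----------------------------------------------------------- minimizer ----
// Steepest descent with clamped per-bead displacement; relaxes overlaps
// from chain growth before dynamics.
// [[Rcpp::export]]
NumericMatrix cpp_minimize(NumericMatrix pos, NumericVector box,
                           IntegerVector type, IntegerMatrix bonds, List ffp,
                           int max_iter = 200, double max_step = 0.2) {
  Sys s = unpack_sys(pos, box, type, bonds);
  FF ff = unpack_ff(ffp);
  double skin = 2.0 + max_step * 20;
  PairList pl;
  build_pairs(s, ff.cut_max + skin, pl);
  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  std::vector<double> refx(s.x), refy(s.y), refz(s.z);
  double moved = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    eval(s, ff, pl, nullptr, &fx, &fy, &fz);
    double fmax = 0.0;
    for (int i = 0; i < s.n; ++i) {
      double f = std::sqrt(fx[i]*fx[i] + fy[i]*fy[i] + fz[i]*fz[i]);
      if (f > fmax) fmax = f;
    }
    if (fmax < 10.0) break;
    double alpha = max_step / fmax;
    for (int i = 0; i < s.n; ++i) {
      s.x[i] += alpha * fx[i]; s.y[i] += alpha * fy[i]; s.z[i] += alpha * fz[i];
    }
    moved += max_step;
    if (moved > 0.45 * skin) {
      build_pairs(s, ff.cut_max + skin, pl);
      moved = 0.0;
    }
  }
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    out(i, 0) = s.x[i] - s.bx * std::floor(s.x[i] / s.bx);
    out(i, 1) = s.y[i] - s.by * std::floor(s.y[i] / s.by);
    out(i, 2) = s.z[i] - s.bz * std::floor(s.z[i] / s.bz);
  }
  return out;
}

// ------------------------------------------- packed lists (integrator) ----
// Split, parameter-packed pair lists: the vdW list holds every nonbonded
// pair within cutoff_vdw + skin with premixed sigma^2 and lambda; the
// electrostatic list holds only charged-charged pairs within
// cutoff_elec + skin with the premultiplied charge product.
struct PackedLists {
  std::vector<int> va, vb;
  std::vector<double> vsig2, vlam;
  std::vector<int> ea, eb;
  std::vector<double> eqq;
};

static void build_packed(const Sys& s, const FF& ff, double skin,
                         PackedLists& L) {
  PairList pl;
  build_pairs(s, ff.cut_max + skin, pl);
  L.va.clear(); L.vb.clear(); L.vsig2.clear(); L.vlam.clear();
  L.ea.clear(); L.eb.clear(); L.eqq.clear();
  double r2v = (ff.cut_vdw + skin) * (ff.cut_vdw + skin);
  double r2e = (ff.cut_elec + skin) * (ff.cut_elec + skin);
  for (size_t p = 0; p < pl.a.size(); ++p) {
    int i = pl.a[p], j = pl.b[p];
    if (excluded(s, i, j)) continue;
    double dx = mind(s.x[i] - s.x[j], s.bx);
    double dy = mind(s.y[i] - s.y[j], s.by);
    double dz = mind(s.z[i] - s.z[j], s.bz);
    double r2 = dx * dx + dy * dy + dz * dz;
    int ti = s.type[i], tj = s.type[j];
    if (r2 < r2v) {
      double sig = 0.5 * (ff.sigma[ti] + ff.sigma[tj]);
      L.va.push_back(i); L.vb.push_back(j);
      L.vsig2.push_back(sig * sig);
      L.vlam.push_back(0.5 * (ff.lambda[ti] + ff.lambda[tj]));
    }
    double qq = ff.q[ti] * ff.q[tj];
    if (qq != 0.0 && r2 < r2e) {
      L.ea.push_back(i); L.eb.push_back(j); L.eqq.push_back(qq);
    }
  }
}

static void eval_packed(const Sys& s, const FF& ff, const PackedLists& L,
                        const ElecTable& et,
                        std::vector<double>& fx, std::vector<double>& fy,
                        std::vector<double>& fz) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double c2v = ff.cut_vdw * ff.cut_vdw, c2e = ff.cut_elec * ff.cut_elec;
  double cbrt2 = std::pow(2.0, 1.0 / 3.0);
  double inv_kappa = 1.0 / ff.kappa;
  double bx = s.bx, by = s.by, bz = s.bz;
  double ibx = 1.0 / bx, iby = 1.0 / by, ibz = 1.0 / bz;
  size_t nv = L.va.size();
  for (size_t p = 0; p < nv; ++p) {
    int i = L.va[p], j = L.vb[p];
    double dx = mindi(s.x[i] - s.x[j], bx, ibx);
    double dy = mindi(s.y[i] - s.y[j], by, iby);
    double dz = mindi(s.z[i] - s.z[j], bz, ibz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= c2v) continue;
    double inv_r2 = 1.0 / r2;
    double sr2 = L.vsig2[p] * inv_r2;
    double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
    double flj = 24.0 * ff.eps * (2.0 * sr12 - sr6) * inv_r2;
    double f_over_r = (r2 <= cbrt2 * L.vsig2[p]) ? flj : L.vlam[p] * flj;
    fx[i] += f_over_r * dx; fx[j] -= f_over_r * dx;
    fy[i] += f_over_r * dy; fy[j] -= f_over_r * dy;
    fz[i] += f_over_r * dz; fz[j] -= f_over_r * dz;
  }
  size_t ne = L.ea.size();
  for (size_t p = 0; p < ne; ++p) {
    int i = L.ea[p], j = L.eb[p];
    double dx = mindi(s.x[i] - s.x[j], bx, ibx);
    double dy = mindi(s.y[i] - s.y[j], by, iby);
    double dz = mindi(s.z[i] - s.z[j], bz, ibz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= c2e) continue;
    double r = std::sqrt(r2);
    double u = ff.kq * L.eqq[p] * et.eval(r);
    double f_over_r = u * (1.0 / r + inv_kappa) / r;
    fx[i] += f_over_r * dx; fx[j] -= f_over_r * dx;
    fy[i] += f_over_r * dy; fy[j] -= f_over_r * dy;
    fz[i] += f_over_r * dz; fz[j] -= f_over_r * dz;
  }
  for (size_t b = 0; b < s.bondA.size(); ++b) {
    int i = s.bondA[b], j = s.bondB[b];
    double dx = mind(s.x[i] - s.x[j], s.bx);
    double dy = mind(s.y[i] - s.y[j], s.by);
    double dz = mind(s.z[i] - s.z[j], s.bz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double f_over_r = -ff.bond_k * (r - ff.bond_r0) / r;
    fx[i] += f_over_r * dx; fx[j] -= f_over_r * dx;
    fy[i] += f_over_r * dy; fy[j] -= f_over_r * dy;
    fz[i] += f_over_r * dz; fz[j] -= f_over_r * dz;
  }
}

// ---------------------------------------------------------- integrator ----
// BAOAB splitting; friction gamma in 1/ps, dt in ps, T in K.
// [[Rcpp::export]]
List cpp_langevin(NumericMatrix pos, NumericVector box, IntegerVector type,
                  IntegerMatrix bonds, List ffp, int n_steps, double dt,
                  double temperature, double friction, int stride,
                  double seed, Nullable<NumericMatrix> vel0,
                  double skin = 3.0) {
  Sys s = unpack_sys(pos, box, type, bonds);
  FF ff = unpack_ff(ffp);
  int n = s.n;
  Rng rng((uint64_t)seed);
  // per-bead constants
  std::vector<double> inv_m(n), vth(n);
  for (int i = 0; i < n; ++i) {
    double m = ff.mass[s.type[i]];
    inv_m[i] = 1.0 / (m * MV2_TO_KJ);               // a = F * inv_m
    vth[i] = std::sqrt(temperature * KB / (m * MV2_TO_KJ));
  }
  std::vector<double> vx(n), vy(n), vz(n);
  if (vel0.isNotNull()) {
    NumericMatrix v(vel0);
    for (int i = 0; i < n; ++i) { vx[i] = v(i,0); vy[i] = v(i,1); vz[i] = v(i,2); }
  } else {
    for (int i = 0; i < n; ++i) {
      vx[i] = vth[i] * rng.gauss(); vy[i] = vth[i] * rng.gauss();
      vz[i] = vth[i] * rng.gauss();
    }
  }
  ElecTable et;
  et.init(ff.kappa, ff.cut_elec);
  PackedLists L;
  build_packed(s, ff, skin, L);
  std::vector<double> fx(n), fy(n), fz(n);
  eval_packed(s, ff, L, et, fx, fy, fz);
  std::vector<double> refx(s.x), refy(s.y), refz(s.z);

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  int nsave = (stride > 0) ? n_steps / stride : 0;
  NumericVector frames(Dimension(n, 3, nsave));
  NumericVector times(nsave), temps(nsave);
  int isave = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * fx[i] * inv_m[i];
      vy[i] += 0.5 * dt * fy[i] * inv_m[i];
      vz[i] += 0.5 * dt * fz[i] * inv_m[i];
      s.x[i] += 0.5 * dt * vx[i]; s.y[i] += 0.5 * dt * vy[i]; s.z[i] += 0.5 * dt * vz[i];
      if (friction > 0) {
        vx[i] = c1 * vx[i] + c2 * vth[i] * rng.gauss();
        vy[i] = c1 * vy[i] + c2 * vth[i] * rng.gauss();
        vz[i] = c1 * vz[i] + c2 * vth[i] * rng.gauss();
      }
      s.x[i] += 0.5 * dt * vx[i]; s.y[i] += 0.5 * dt * vy[i]; s.z[i] += 0.5 * dt * vz[i];
    }
    double maxd2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = s.x[i] - refx[i], dy = s.y[i] - refy[i], dz = s.z[i] - refz[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > maxd2) maxd2 = d2;
    }
    if (maxd2 > 0.25 * skin * skin) {
      build_packed(s, ff, skin, L);
      refx = s.x; refy = s.y; refz = s.z;
    }
    eval_packed(s, ff, L, et, fx, fy, fz);
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(fx[i]) || !std::isfinite(fy[i]) || !std::isfinite(fz[i]) ||
          std::fabs(fx[i]) > 1e7 || std::fabs(fy[i]) > 1e7 || std::fabs(fz[i]) > 1e7) {
        std::ostringstream msg;
        msg << "force overflow on bead " << (i + 1) << " at step " << step
            << " (check timestep / initial overlaps)";
        stop(msg.str());
      }
      vx[i] += 0.5 * dt * fx[i] * inv_m[i];
      vy[i] += 0.5 * dt * fy[i] * inv_m[i];
      vz[i] += 0.5 * dt * fz[i] * inv_m[i];
    }
    if (stride > 0 && step % stride == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * ff.mass[s.type[i]] * MV2_TO_KJ *
              (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      temps[isave] = 2.0 * ke / (3.0 * n * KB);
      times[isave] = step * dt;
      for (int i = 0; i < n; ++i) {
        frames[isave * 3 * n + 0 * n + i] = s.x[i] - s.bx * std::floor(s.x[i] / s.bx);
        frames[isave * 3 * n + 1 * n + i] = s.y[i] - s.by * std::floor(s.y[i] / s.by);
        frames[isave * 3 * n + 2 * n + i] = s.z[i] - s.bz * std::floor(s.z[i] / s.bz);
      }
      ++isave;
    }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix posOut(n, 3), velOut(n, 3);
  for (int i = 0; i < n; ++i) {
    posOut(i, 0) = s.x[i] - s.bx * std::floor(s.x[i] / s.bx);
    posOut(i, 1) = s.y[i] - s.by * std::floor(s.y[i] / s.by);
    posOut(i, 2) = s.z[i] - s.bz * std::floor(s.z[i] / s.bz);
    velOut(i, 0) = vx[i]; velOut(i, 1) = vy[i]; velOut(i, 2) = vz[i];
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["temperatures"] = temps, _["positions"] = posOut,
                      _["velocities"] = velOut);
}

// ------------------------------------------------------------ contacts ----
// Bead pairs within a distance criterion.  If sigma has length n, the
// threshold for pair (i, j) is 2^(1/6) * (sigma_i + sigma_j) / 2; otherwise
// the fixed cutoff is used.  Strict inequality; 1-based pairs (i < j).
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, NumericVector box,
                                double cutoff, NumericVector sigma) {
  int n = pos.nrow();
  bool sigrule = sigma.size() == n;
  double sixth = std::pow(2.0, 1.0 / 6.0);
  double rmax = cutoff;
  if (sigrule) {
    double smax = 0.0;
    for (int i = 0; i < n; ++i) smax = std::max(smax, sigma[i]);
    rmax = sixth * smax;
  }
  Sys s;
  s.n = n; s.x.resize(n); s.y.resize(n); s.z.resize(n);
  for (int i = 0; i < n; ++i) { s.x[i] = pos(i,0); s.y[i] = pos(i,1); s.z[i] = pos(i,2); }
  s.bx = box[0]; s.by = box[1]; s.bz = box[2];
  PairList pl;
  build_pairs(s, rmax, pl);
  std::vector<int> ia, ja;
  for (size_t p = 0; p < pl.a.size(); ++p) {
    int i = pl.a[p], j = pl.b[p];
    double dx = mind(s.x[i]-s.x[j], s.bx), dy = mind(s.y[i]-s.y[j], s.by),
           dz = mind(s.z[i]-s.z[j], s.bz);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double thr = sigrule ? sixth * 0.5 * (sigma[i] + sigma[j]) : cutoff;
    if (r < thr) { ia.push_back(i + 1); ja.push_back(j + 1); }
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t k = 0; k < ia.size(); ++k) { out(k, 0) = ia[k]; out(k, 1) = ja[k]; }
  return out;
}
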