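// Coarse-grained force field + BAOAB Langevin propagation.
//
// Units package-wide: A, ps, kcal/mol, K, amu.  Acceleration conversion:
// 1 kcal/mol/A / amu = 418.4 A/ps^2.  Harmonic terms use the Amber-style
// form E = k (x - x0)^2 (no 1/2), matching the disulfide restraint
// alpha * k_d * (r_SS - r0_SS)^2.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KB_KCAL = 0.0019872041; // kcal/mol/K
static const double ACC = 418.4;            // (kcal/mol/A)/amu -> A/ps^2

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ with explicit 32-byte state so frames can be replayed
// bitwise.  Normals via Box-Muller without caching (state is pure 4x uint64).
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // open (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    const double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  // Box-Muller pair; callers consuming an even run of normals use both
  // values so the 32-byte state fully captures the stream between steps.
  inline void norm2(double& a, double& b) {
    const double u1 = unif(), u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    a = r * std::cos(2.0 * M_PI * u2);
    b = r * std::sin(2.0 * M_PI * u2);
  }
};

static void seed_state(Xoshiro& g, uint64_t seed) {
  uint64_t z = seed; // splitmix64 expansion
  for (int i = 0; i < 4; ++i) {
    z += 0x9e3779b97f4a7c15ULL;
    uint64_t x = z;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    g.s[i] = x ^ (x >> 31);
  }
}

static RawVector state_to_raw(const Xoshiro& g) {
  RawVector r(32);
  std::memcpy(RAW(r), g.s, 32);
  return r;
}

static void raw_to_state(Xoshiro& g, const RawVector& r) {
  if (r.size() != 32) stop("rng state must be exactly 32 bytes");
  std::memcpy(g.s, RAW(r), 32);
}

// [[Rcpp::export]]
RawVector rng_seed_cpp(double seed) {
  Xoshiro g;
  seed_state(g, (uint64_t)seed);
  return state_to_raw(g);
}

// [[Rcpp::export]]
NumericVector rng_unif_cpp(RawVector state, int n) {
  Xoshiro g;
  raw_to_state(g, state);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g.unif();
  out.attr("state") = state_to_raw(g);
  return out;
}

// ---------------------------------------------------------------------------
// Force field container
// ---------------------------------------------------------------------------
struct FF {
  int n;
  std::vector<double> mass;
  // bonded terms
  std::vector<int> bi, bj;          std::vector<double> bk, br0;
  std::vector<int> ai, aj, ak;      std::vector<double> akf, at0;
  std::vector<int> di, dj, dk, dl;  std::vector<double> dkf, dp0;
  // LJ
  double eps, r0, r0s, cut2;
  std::vector<int> status; // n*n: 0 skip, 1 normal r0, 2 shrunk r0
  double sphere;           // reflective sphere radius (<=0 disables)
  // alpha-scaled restraints
  std::vector<int> rdi, rdj;             std::vector<double> rdk, rdr0;
  std::vector<int> rai, raj, rak;        std::vector<double> rakf, rat0;
  std::vector<int> rhi, rhj, rhk, rhl;   std::vector<double> rhkf, rhp0;
};

static std::vector<int> idx0(const IntegerVector& v, int n) {
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) {
    if (v[i] < 1 || v[i] > n)
      stop("particle index %d out of range [1, %d]", v[i], n);
    out[i] = v[i] - 1;
  }
  return out;
}

static std::vector<double> dvec(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

static FF parse_ff(const List& ff, const List& restraints) {
  FF f;
  NumericVector mass = ff["mass"];
  f.n = mass.size();
  f.mass = dvec(mass);
  f.bi = idx0(ff["bond_i"], f.n); f.bj = idx0(ff["bond_j"], f.n);
  f.bk = dvec(ff["bond_k"]);      f.br0 = dvec(ff["bond_r0"]);
  f.ai = idx0(ff["angle_i"], f.n); f.aj = idx0(ff["angle_j"], f.n);
  f.ak = idx0(ff["angle_k"], f.n);
  f.akf = dvec(ff["angle_kf"]);    f.at0 = dvec(ff["angle_t0"]); // radians
  f.di = idx0(ff["dihedral_i"], f.n); f.dj = idx0(ff["dihedral_j"], f.n);
  f.dk = idx0(ff["dihedral_k"], f.n); f.dl = idx0(ff["dihedral_l"], f.n);
  f.dkf = dvec(ff["dihedral_kf"]);    f.dp0 = dvec(ff["dihedral_p0"]);
  f.eps = as<double>(ff["lj_eps"]);
  f.r0 = as<double>(ff["lj_r0"]);
  f.r0s = as<double>(ff["lj_r0_shrunk"]);
  double cut = as<double>(ff["lj_cutoff"]);
  f.cut2 = cut * cut;
  IntegerMatrix st = ff["lj_status"];
  if (st.nrow() != f.n || st.ncol() != f.n) stop("lj_status must be n x n");
  f.status.assign(st.begin(), st.end());
  f.sphere = as<double>(ff["sphere_radius"]);
  f.rdi = idx0(restraints["dist_i"], f.n); f.rdj = idx0(restraints["dist_j"], f.n);
  f.rdk = dvec(restraints["dist_k"]);      f.rdr0 = dvec(restraints["dist_r0"]);
  f.rai = idx0(restraints["angle_i"], f.n); f.raj = idx0(restraints["angle_j"], f.n);
  f.rak = idx0(restraints["angle_k"], f.n);
  f.rakf = dvec(restraints["angle_kf"]);    f.rat0 = dvec(restraints["angle_t0"]);
  f.rhi = idx0(restraints["dihedral_i"], f.n); f.rhj = idx0(restraints["dihedral_j"], f.n);
  f.rhk = idx0(restraints["dihedral_k"], f.n); f.rhl = idx0(restraints["dihedral_l"], f.n);
  f.rhkf = dvec(restraints["dihedral_kf"]);    f.rhp0 = dvec(restraints["dihedral_p0"]);
  return f;
}

// ---------------------------------------------------------------------------
// Energy terms.  All add gradient contributions into f (force = -grad).
// ---------------------------------------------------------------------------
static inline void dist_term(const double* x, int i, int j, double k,
                             double r0, double scale, double& E, double* f) {
  const double dx = x[3 * i] - x[3 * j];
  const double dy = x[3 * i + 1] - x[3 * j + 1];
  const double dz = x[3 * i + 2] - x[3 * j + 2];
  const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (r < 1e-6)
    stop("invalid geometry: particles %d and %d overlap", i + 1, j + 1);
  const double d = r - r0;
  E += scale * k * d * d;
  const double c = -2.0 * scale * k * d / r; // force factor along (ri - rj)
  f[3 * i] += c * dx; f[3 * i + 1] += c * dy; f[3 * i + 2] += c * dz;
  f[3 * j] -= c * dx; f[3 * j + 1] -= c * dy; f[3 * j + 2] -= c * dz;
}

static inline void angle_term(const double* x, int i, int j, int k, double kf,
                              double t0, double scale, double& E, double* f) {
  double u[3], v[3];
  for (int c = 0; c < 3; ++c) {
    u[c] = x[3 * i + c] - x[3 * j + c];
    v[c] = x[3 * k + c] - x[3 * j + c];
  }
  const double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  const double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (nu < 1e-6 || nv < 1e-6)
    stop("invalid geometry in angle term %d-%d-%d", i + 1, j + 1, k + 1);
  double ct = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (nu * nv);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  const double theta = std::acos(ct);
  double st = std::sqrt(1.0 - ct * ct);
  if (st < 1e-8) st = 1e-8;
  const double dE = 2.0 * scale * kf * (theta - t0);
  E += scale * kf * (theta - t0) * (theta - t0);
  for (int c = 0; c < 3; ++c) {
    const double dti = -(v[c] / (nu * nv) - ct * u[c] / (nu * nu)) / st;
    const double dtk = -(u[c] / (nu * nv) - ct * v[c] / (nv * nv)) / st;
    f[3 * i + c] -= dE * dti;
    f[3 * k + c] -= dE * dtk;
    f[3 * j + c] += dE * (dti + dtk);
  }
}

static inline double wrap_pi(double d) {
  while (d > M_PI) d -= 2.0 * M_PI;
  while (d <= -M_PI) d += 2.0 * M_PI;
  return d;
}

static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

static inline void dihedral_term(const double* x, int i, int j, int k, int l,
                                 double kf, double p0, double scale, double& E,
                                 double* f) {
  double b1[3], b2[3], b3[3];
  for (int c = 0; c < 3; ++c) {
    b1[c] = x[3 * j + c] - x[3 * i + c];
    b2[c] = x[3 * k + c] - x[3 * j + c];
    b3[c] = x[3 * l + c] - x[3 * k + c];
  }
  double n1[3], n2[3], m1[3];
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  const double b2n = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  if (b2n < 1e-6)
    stop("invalid geometry in dihedral term %d-%d-%d-%d", i + 1, j + 1, k + 1, l + 1);
  cross3(n1, n2, m1);
  const double sinp = (m1[0] * b2[0] + m1[1] * b2[1] + m1[2] * b2[2]) / b2n;
  const double cosp = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  const double phi = std::atan2(sinp, cosp);
  const double d = wrap_pi(phi - p0); // shortest-arc deviation
  E += scale * kf * d * d;
  const double dE = 2.0 * scale * kf * d;
  double n1sq = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
  double n2sq = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
  if (n1sq < 1e-12) n1sq = 1e-12;
  if (n2sq < 1e-12) n2sq = 1e-12;
  const double p = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (b2n * b2n);
  const double q = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (b2n * b2n);
  for (int c = 0; c < 3; ++c) {
    const double dpi = -(b2n / n1sq) * n1[c];
    const double dpl = (b2n / n2sq) * n2[c];
    const double dpj = -(1.0 + p) * dpi + q * dpl;
    const double dpk = p * dpi - (1.0 + q) * dpl;
    f[3 * i + c] -= dE * dpi;
    f[3 * j + c] -= dE * dpj;
    f[3 * k + c] -= dE * dpk;
    f[3 * l + c] -= dE * dpl;
  }
}

// Fill forces and the 5-way energy breakdown.
static void compute(const FF& ff, const double* x, double alpha, double* f,
                    double* ener) {
  const int n = ff.n;
  for (int i = 0; i < 3 * n; ++i) f[i] = 0.0;
  for (int i = 0; i < 5; ++i) ener[i] = 0.0;
  for (size_t t = 0; t < ff.bi.size(); ++t)
    dist_term(x, ff.bi[t], ff.bj[t], ff.bk[t], ff.br0[t], 1.0, ener[0], f);
  for (size_t t = 0; t < ff.ai.size(); ++t)
    angle_term(x, ff.ai[t], ff.aj[t], ff.ak[t], ff.akf[t], ff.at0[t], 1.0,
               ener[1], f);
  for (size_t t = 0; t < ff.di.size(); ++t)
    dihedral_term(x, ff.di[t], ff.dj[t], ff.dk[t], ff.dl[t], ff.dkf[t],
                  ff.dp0[t], 1.0, ener[2], f);
  // Lennard-Jones, truncated (not shifted) at the cutoff
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int st = ff.status[i * n + j];
      if (st == 0) continue;
      const double dx = x[3 * i] - x[3 * j];
      const double dy = x[3 * i + 1] - x[3 * j + 1];
      const double dz = x[3 * i + 2] - x[3 * j + 2];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > ff.cut2) continue;
      if (r2 < 1e-12)
        stop("invalid geometry: particles %d and %d overlap", i + 1, j + 1);
      const double r0 = (st == 2) ? ff.r0s : ff.r0;
      const double inv_r2 = 1.0 / r2;
      const double sr2 = (r0 * r0) * inv_r2;
      const double sr6 = sr2 * sr2 * sr2;
      const double sr12 = sr6 * sr6;
      ener[3] += ff.eps * (sr12 - 2.0 * sr6);
      const double c = 12.0 * ff.eps * (sr12 - sr6) * inv_r2; // -dE/dr / r
      f[3 * i] += c * dx; f[3 * i + 1] += c * dy; f[3 * i + 2] += c * dz;
      f[3 * j] -= c * dx; f[3 * j + 1] -= c * dy; f[3 * j + 2] -= c * dz;
    }
  }
  if (alpha > 0.0) {
    for (size_t t = 0; t < ff.rdi.size(); ++t)
      dist_term(x, ff.rdi[t], ff.rdj[t], ff.rdk[t], ff.rdr0[t], alpha,
                ener[4], f);
    for (size_t t = 0; t < ff.rai.size(); ++t)
      angle_term(x, ff.rai[t], ff.raj[t], ff.rak[t], ff.rakf[t], ff.rat0[t],
                 alpha, ener[4], f);
    for (size_t t = 0; t < ff.rhi.size(); ++t)
      dihedral_term(x, ff.rhi[t], ff.rhj[t], ff.rhk[t], ff.rhl[t], ff.rhkf[t],
                    ff.rhp0[t], alpha, ener[4], f);
  }
}

// [[Rcpp::export]]
List cg_compute_cpp(NumericMatrix pos, List ff_list, List restraints,
                    double alpha, bool want_forces) {
  FF ff = parse_ff(ff_list, restraints);
  if (pos.nrow() != ff.n) stop("positions do not match topology size");
  std::vector<double> x(3 * ff.n), f(3 * ff.n);
  for (int i = 0; i < ff.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);
  double ener[5];
  compute(ff, x.data(), alpha, f.data(), ener);
  List out = List::create(
      _["bond"] = ener[0], _["angle"] = ener[1], _["dihedral"] = ener[2],
      _["lj"] = ener[3], _["restraint"] = ener[4],
      _["total"] = ener[0] + ener[1] + ener[2] + ener[3] + ener[4]);
  if (want_forces) {
    NumericMatrix fm(ff.n, 3);
    for (int i = 0; i < ff.n; ++i)
      for (int c = 0; c < 3; ++c) fm(i, c) = f[3 * i + c];
    out["forces"] = fm;
  }
  return out;
}

// ---------------------------------------------------------------------------
// BAOAB Langevin propagation.  gamma = 0 reduces exactly to velocity Verlet
// (the O step is skipped, so no RNG is consumed).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix pos, NumericMatrix vel, List ff_list,
                List restraints, double alpha, int n_steps, int save_every,
                double dt, double gamma, double temperature,
                RawVector rng_state) {
  FF ff = parse_ff(ff_list, restraints);
  const int n = ff.n;
  if (pos.nrow() != n || vel.nrow() != n)
    stop("positions/velocities do not match topology size");
  if (n_steps % save_every != 0)
    stop("n_steps must be a multiple of save_every");
  const int n_frames = n_steps / save_every;

  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      x[3 * i + c] = pos(i, c);
      v[3 * i + c] = vel(i, c);
    }
  Xoshiro rng;
  raw_to_state(rng, rng_state);

  std::vector<double> hdt(n), sig(n);
  const double c1 = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  for (int i = 0; i < n; ++i) {
    hdt[i] = 0.5 * dt * ACC / ff.mass[i];
    sig[i] = (gamma > 0.0)
                 ? std::sqrt(KB_KCAL * temperature * ACC * (1.0 - c1 * c1) /
                             ff.mass[i])
                 : 0.0;
  }

  NumericVector pos_out(Dimension(n, 3, n_frames));
  NumericVector vel_out(Dimension(n, 3, n_frames));
  List rng_out(n_frames);

  double ener[5];
  compute(ff, x.data(), alpha, f.data(), ener);
  int saved = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] += hdt[i] * f[3 * i + c];
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (gamma > 0.0) {
      // consume normals in pairs; any odd tail value is drawn singly so the
      // per-step draw count is fixed and the state saves cleanly
      double g1, g2;
      const int ndof = 3 * n;
      for (int d = 0; d + 1 < ndof; d += 2) {
        rng.norm2(g1, g2);
        v[d] = c1 * v[d] + sig[d / 3] * g1;
        v[d + 1] = c1 * v[d + 1] + sig[(d + 1) / 3] * g2;
      }
      if (ndof % 2) v[ndof - 1] = c1 * v[ndof - 1] + sig[n - 1] * rng.norm();
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (ff.sphere > 0.0) {
      for (int i = 0; i < n; ++i) {
        const double rr = std::sqrt(x[3 * i] * x[3 * i] +
                                    x[3 * i + 1] * x[3 * i + 1] +
                                    x[3 * i + 2] * x[3 * i + 2]);
        if (rr > ff.sphere) {
          const double scale = (2.0 * ff.sphere - rr) / rr;
          double rad = 0.0;
          for (int c = 0; c < 3; ++c) rad += v[3 * i + c] * x[3 * i + c] / rr;
          for (int c = 0; c < 3; ++c) {
            const double rhat = x[3 * i + c] / rr;
            if (rad > 0.0) v[3 * i + c] -= 2.0 * rad * rhat;
            x[3 * i + c] *= scale;
          }
        }
      }
    }
    compute(ff, x.data(), alpha, f.data(), ener);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] += hdt[i] * f[3 * i + c];

    if (step % save_every == 0) {
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(x[i]))
          stop("integration blew up at step %d (non-finite coordinates)", step);
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c) {
          pos_out[saved * 3 * n + c * n + i] = x[3 * i + c];
          vel_out[saved * 3 * n + c * n + i] = v[3 * i + c];
        }
      rng_out[saved] = state_to_raw(rng);
      ++saved;
    }
  }
  return List::create(_["positions"] = pos_out, _["velocities"] = vel_out,
                      _["rng"] = rng_out, _["n_frames"] = n_frames);
}
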