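// Minimal structure-based (Go-type) Langevin dynamics engine.
//
// Reduced units: energy in units of the native-contact well depth (epsilon),
// length in nm, mass 1 per bead, k_B = 1.  Time is the LJ time unit.
//
// Potential terms:
//   bonds      V = kb/2 (r - r0)^2
//   angles     V = ka/2 (theta - theta0)^2
//   dihedrals  V = kd [ (1 - cos(phi - phi0)) + 1/2 (1 - cos 3(phi - phi0)) ]
//   native     V = eps [ 5 (r0/r)^12 - 6 (r0/r)^10 ]      (10-12 form)
//   non-native V = eps_nc (sigma/r)^12, truncated and shifted at rc
//
// Integrator: BAOAB Langevin splitting; gamma = 0, T = 0 reduces exactly to
// velocity Verlet, which is what the energy-conservation checks exercise.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

namespace {

// splitmix64-seeded xoshiro256+ with Box-Muller normals: deterministic
// across platforms, independent of R's RNG.
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

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
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double a) const { return Vec3(x * a, y * a, z * a); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

struct Model {
  int n;
  std::vector<int> bi, bj;                 std::vector<double> br0, bk;
  std::vector<int> ai, aj, ak;             std::vector<double> ath0, aka;
  std::vector<int> di, dj, dk, dl;         std::vector<double> dphi0, dkd;
  std::vector<int> pi_, pj_;               std::vector<double> pr0, peps;
  double sigma_nc, eps_nc, rc_nc, shift_nc;
  int excl_sep;                            // |i-j| <= excl_sep excluded from repulsion
  std::unordered_set<int64_t> native_set;  // native pairs excluded from repulsion
};

Model parse_model(const List& m) {
  Model M;
  M.n = as<int>(m["n"]);
  IntegerMatrix B = m["bonds"];      NumericMatrix Bp = m["bond_params"];
  for (int r = 0; r < B.nrow(); ++r) {
    M.bi.push_back(B(r, 0) - 1); M.bj.push_back(B(r, 1) - 1);
    M.br0.push_back(Bp(r, 0));   M.bk.push_back(Bp(r, 1));
  }
  IntegerMatrix A = m["angles"];     NumericMatrix Ap = m["angle_params"];
  for (int r = 0; r < A.nrow(); ++r) {
    M.ai.push_back(A(r, 0) - 1); M.aj.push_back(A(r, 1) - 1); M.ak.push_back(A(r, 2) - 1);
    M.ath0.push_back(Ap(r, 0));  M.aka.push_back(Ap(r, 1));
  }
  IntegerMatrix D = m["dihedrals"];  NumericMatrix Dp = m["dihedral_params"];
  for (int r = 0; r < D.nrow(); ++r) {
    M.di.push_back(D(r, 0) - 1); M.dj.push_back(D(r, 1) - 1);
    M.dk.push_back(D(r, 2) - 1); M.dl.push_back(D(r, 3) - 1);
    M.dphi0.push_back(Dp(r, 0)); M.dkd.push_back(Dp(r, 1));
  }
  IntegerMatrix P = m["pairs"];      NumericMatrix Pp = m["pair_params"];
  for (int r = 0; r < P.nrow(); ++r) {
    int i = P(r, 0) - 1, j = P(r, 1) - 1;
    M.pi_.push_back(i); M.pj_.push_back(j);
    M.pr0.push_back(Pp(r, 0)); M.peps.push_back(Pp(r, 1));
    M.native_set.insert((int64_t)std::min(i, j) * M.n + std::max(i, j));
  }
  M.sigma_nc = as<double>(m["sigma_nc"]);
  M.eps_nc   = as<double>(m["eps_nc"]);
  M.rc_nc    = as<double>(m["rc_nc"]);
  M.excl_sep = as<int>(m["excl_sep"]);
  double sr = M.sigma_nc / M.rc_nc;
  M.shift_nc = M.eps_nc * std::pow(sr, 12);
  return M;
}

double dihedral_angle(const Vec3& b1, const Vec3& b2, const Vec3& b3,
                      Vec3& mvec, Vec3& nvec) {
  mvec = b1.cross(b2);
  nvec = b2.cross(b3);
  double b2n = b2.norm();
  double x = mvec.dot(nvec);
  double y = (mvec.cross(nvec)).dot(b2) / std::max(b2n, 1e-12);
  return std::atan2(y, x);
}

// Potential energy and forces (forces accumulated into f).
double compute_forces(const Model& M, const std::vector<Vec3>& x,
                      std::vector<Vec3>& f, bool want_forces = true) {
  double pe = 0.0;
  if (want_forces) for (auto& v : f) v = Vec3();

  // bonds
  for (size_t t = 0; t < M.bi.size(); ++t) {
    Vec3 d = x[M.bi[t]] - x[M.bj[t]];
    double r = d.norm();
    double dr = r - M.br0[t];
    pe += 0.5 * M.bk[t] * dr * dr;
    if (want_forces && r > 1e-12) {
      Vec3 fr = d * (-M.bk[t] * dr / r);
      f[M.bi[t]] = f[M.bi[t]] + fr;
      f[M.bj[t]] = f[M.bj[t]] - fr;
    }
  }
  // angles
  for (size_t t = 0; t < M.ai.size(); ++t) {
    const Vec3& ri = x[M.ai[t]]; const Vec3& rj = x[M.aj[t]]; const Vec3& rk = x[M.ak[t]];
    Vec3 u = ri - rj, w = rk - rj;
    double lu = u.norm(), lw = w.norm();
    if (lu < 1e-12 || lw < 1e-12) continue;
    Vec3 nu = u * (1.0 / lu), nw = w * (1.0 / lw);
    double c = std::min(1.0, std::max(-1.0, nu.dot(nw)));
    double s = std::sqrt(std::max(1.0 - c * c, 1e-12));
    double th = std::acos(c);
    double dth = th - M.ath0[t];
    pe += 0.5 * M.aka[t] * dth * dth;
    if (want_forces) {
      double dV = M.aka[t] * dth;
      // d(theta)/dri = (c*nu - nw) / (lu * s) ; similarly for rk
      Vec3 gi = (nu * c - nw) * (1.0 / (lu * s));
      Vec3 gk = (nw * c - nu) * (1.0 / (lw * s));
      Vec3 fi = gi * (-dV);
      Vec3 fk = gk * (-dV);
      f[M.ai[t]] = f[M.ai[t]] + fi;
      f[M.ak[t]] = f[M.ak[t]] + fk;
      f[M.aj[t]] = f[M.aj[t]] - fi - fk;
    }
  }
  // dihedrals
  for (size_t t = 0; t < M.di.size(); ++t) {
    const Vec3& ri = x[M.di[t]]; const Vec3& rj = x[M.dj[t]];
    const Vec3& rk = x[M.dk[t]]; const Vec3& rl = x[M.dl[t]];
    Vec3 b1 = rj - ri, b2 = rk - rj, b3 = rl - rk;
    Vec3 mvec, nvec;
    double phi = dihedral_angle(b1, b2, b3, mvec, nvec);
    double dphi = phi - M.dphi0[t];
    pe += M.dkd[t] * ((1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0 * dphi)));
    if (want_forces) {
      double dV = M.dkd[t] * (std::sin(dphi) + 1.5 * std::sin(3.0 * dphi));
      double m2 = mvec.dot(mvec), n2 = nvec.dot(nvec);
      double b2n = b2.norm();
      if (m2 < 1e-16 || n2 < 1e-16 || b2n < 1e-12) continue;
      // gradients of phi w.r.t. the four positions (standard formulation)
      Vec3 g1 = mvec * (-b2n / m2);
      Vec3 g4 = nvec * ( b2n / n2);
      double p = b1.dot(b2) / (b2n * b2n);
      double q = b3.dot(b2) / (b2n * b2n);
      Vec3 g2 = g1 * (-p - 1.0) + g4 * q;
      Vec3 g3 = g4 * (-q - 1.0) + g1 * p;
      f[M.di[t]] = f[M.di[t]] + g1 * (-dV);
      f[M.dj[t]] = f[M.dj[t]] + g2 * (-dV);
      f[M.dk[t]] = f[M.dk[t]] + g3 * (-dV);
      f[M.dl[t]] = f[M.dl[t]] + g4 * (-dV);
    }
  }
  // native 10-12 pairs
  for (size_t t = 0; t < M.pi_.size(); ++t) {
    Vec3 d = x[M.pi_[t]] - x[M.pj_[t]];
    double r = d.norm();
    if (r < 1e-12) continue;
    double s = M.pr0[t] / r;
    double s10 = std::pow(s, 10), s12 = s10 * s * s;
    pe += M.peps[t] * (5.0 * s12 - 6.0 * s10);
    if (want_forces) {
      double fr = M.peps[t] * 60.0 * (s12 - s10) / r;  // -dU/dr
      Vec3 fv = d * (fr / r);
      f[M.pi_[t]] = f[M.pi_[t]] + fv;
      f[M.pj_[t]] = f[M.pj_[t]] - fv;
    }
  }
  // non-native repulsion (all pairs beyond excl_sep that are not native)
  double rc2 = M.rc_nc * M.rc_nc;
  for (int i = 0; i < M.n; ++i) {
    for (int j = i + M.excl_sep + 1; j < M.n; ++j) {
      Vec3 d = x[i] - x[j];
      double r2 = d.dot(d);
      if (r2 >= rc2) continue;
      if (M.native_set.count((int64_t)i * M.n + j)) continue;
      double r = std::sqrt(r2);
      double s12 = std::pow(M.sigma_nc / r, 12);
      pe += M.eps_nc * s12 - M.shift_nc;
      if (want_forces) {
        double fr = 12.0 * M.eps_nc * s12 / r;  // -dU/dr (repulsive)
        Vec3 fv = d * (fr / r);
        f[i] = f[i] + fv;
        f[j] = f[j] - fv;
      }
    }
  }
  return pe;
}

}  // namespace

// [[Rcpp::export(name = ".go_energy")]]
List go_energy(List model, NumericMatrix x) {
  Model M = parse_model(model);
  std::vector<Vec3> xs(M.n), f(M.n);
  for (int i = 0; i < M.n; ++i) xs[i] = Vec3(x(i, 0), x(i, 1), x(i, 2));
  double pe = compute_forces(M, xs, f, true);
  NumericMatrix F(M.n, 3);
  for (int i = 0; i < M.n; ++i) { F(i, 0) = f[i].x; F(i, 1) = f[i].y; F(i, 2) = f[i].z; }
  return List::create(_["potential"] = pe, _["forces"] = F);
}

// One engine for all protocols.  `pull` and `restraint` are R NULL or lists.
// pull: k, speed, pulled, fixed, L (stop extension; <=0 disables stop)
// restraint: i, j, k_r, displacement, ramp_steps (target distance ramps from
//            the current pair distance to current+displacement)
// [[Rcpp::export(name = ".go_dynamics")]]
List go_dynamics(List model, NumericMatrix x_in, Nullable<NumericMatrix> v_in,
                 double dt, double gamma, double kT,
                 int n_steps, int report_every, double seed,
                 Nullable<List> pull, Nullable<List> restraint,
                 double t0 = 0.0) {
  Model M = parse_model(model);
  const int n = M.n;
  std::vector<Vec3> x(n), v(n), f(n);
  for (int i = 0; i < n; ++i) x[i] = Vec3(x_in(i, 0), x_in(i, 1), x_in(i, 2));
  if (v_in.isNotNull()) {
    NumericMatrix V(v_in);
    for (int i = 0; i < n; ++i) v[i] = Vec3(V(i, 0), V(i, 1), V(i, 2));
  }
  Rng rng((uint64_t)seed);

  bool do_pull = pull.isNotNull();
  double pk = 0, pv = 0, pL = -1;
  int pulled = -1, fixed = -1;
  Vec3 axis, fixed0, ref0;
  double sep0 = 0;
  if (do_pull) {
    List P(pull);
    pk = as<double>(P["k"]); pv = as<double>(P["speed"]);
    pulled = as<int>(P["pulled"]) - 1; fixed = as<int>(P["fixed"]) - 1;
    pL = as<double>(P["L"]);
    fixed0 = x[fixed];
    ref0 = x[pulled];
    Vec3 d = x[pulled] - x[fixed];
    sep0 = d.norm();
    axis = d * (1.0 / sep0);  // fixed direction, set once at t = 0
  }

  bool do_restr = restraint.isNotNull();
  double rk = 0, rdisp = 0, rd0 = 0;
  int ri_ = -1, rj_ = -1, ramp_steps = 0;
  if (do_restr) {
    List R_(restraint);
    ri_ = as<int>(R_["i"]) - 1; rj_ = as<int>(R_["j"]) - 1;
    rk = as<double>(R_["k_r"]); rdisp = as<double>(R_["displacement"]);
    ramp_steps = as<int>(R_["ramp_steps"]);
    rd0 = (x[ri_] - x[rj_]).norm();
  }

  const double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  const double c2 = (gamma > 0) ? std::sqrt(std::max(0.0, 1.0 - c1 * c1)) : 0.0;
  const double sd = std::sqrt(kT);  // mass 1

  int n_rep_max = n_steps / report_every + 2;
  std::vector<double> times, exts, pfs, pes, kes;
  times.reserve(n_rep_max);
  NumericVector frames((R_xlen_t)n_rep_max * n * 3);

  auto add_steering = [&](std::vector<Vec3>& fo, int step) -> double {
    double ext = NA_REAL;
    if (do_pull) {
      double t = t0 + step * dt;
      Vec3 ref = ref0 + axis * (pv * t);
      Vec3 dp = ref - x[pulled];
      fo[pulled] = fo[pulled] + dp * pk;
      Vec3 df = fixed0 - x[fixed];
      fo[fixed] = fo[fixed] + df * pk;
      ext = (x[pulled] - x[fixed]).norm() - sep0;
    }
    if (do_restr) {
      double frac = ramp_steps > 0 ? std::min(1.0, (double)step / ramp_steps) : 1.0;
      double dt_ = rd0 + rdisp * frac;
      Vec3 d = x[ri_] - x[rj_];
      double r = d.norm();
      if (r > 1e-12) {
        Vec3 fv = d * (-rk * (r - dt_) / r);
        fo[ri_] = fo[ri_] + fv;
        fo[rj_] = fo[rj_] - fv;
      }
    }
    return ext;
  };

  compute_forces(M, x, f, true);
  add_steering(f, 0);

  int n_rep = 0;
  bool aborted = false; int abort_step = -1;
  double last_ext = NA_REAL;

  auto record = [&](int step) {
    double pe = compute_forces(M, x, f, false);
    double ke = 0;
    for (int i = 0; i < n; ++i) ke += 0.5 * v[i].dot(v[i]);
    times.push_back(t0 + step * dt);
    pes.push_back(pe); kes.push_back(ke);
    double ext = NA_REAL, pf = NA_REAL;
    if (do_pull) {
      double t = t0 + step * dt;
      Vec3 ref = ref0 + axis * (pv * t);
      ext = (x[pulled] - x[fixed]).norm() - sep0;
      pf = pk * (ref - x[pulled]).dot(axis);
    }
    exts.push_back(ext); pfs.push_back(pf);
    for (int i = 0; i < n; ++i) {
      frames[(R_xlen_t)n_rep * n * 3 + i] = x[i].x;
      frames[(R_xlen_t)n_rep * n * 3 + n + i] = x[i].y;
      frames[(R_xlen_t)n_rep * n * 3 + 2 * n + i] = x[i].z;
    }
    ++n_rep;
  };

  record(0);
  int last_recorded = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i) v[i] = v[i] + f[i] * (0.5 * dt);
    // A
    for (int i = 0; i < n; ++i) x[i] = x[i] + v[i] * (0.5 * dt);
    // O
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        v[i].x = c1 * v[i].x + c2 * sd * rng.norm();
        v[i].y = c1 * v[i].y + c2 * sd * rng.norm();
        v[i].z = c1 * v[i].z + c2 * sd * rng.norm();
      }
    }
    // A
    for (int i = 0; i < n; ++i) x[i] = x[i] + v[i] * (0.5 * dt);
    // force refresh + B
    compute_forces(M, x, f, true);
    last_ext = add_steering(f, step);
    for (int i = 0; i < n; ++i) v[i] = v[i] + f[i] * (0.5 * dt);

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i].x) || !std::isfinite(x[i].y) || !std::isfinite(x[i].z)) {
        aborted = true; abort_step = step; break;
      }
    }
    if (aborted) break;
    if (step % report_every == 0) { record(step); last_recorded = step; }
    if (do_pull && pL > 0 && !ISNA(last_ext) && last_ext >= pL) {
      if (last_recorded != step) record(step);  // terminal frame at >= L
      break;
    }
  }
  if (aborted)
    stop("non-finite coordinates at step %d; reduce the time step or check the model",
         abort_step);

  NumericVector fr_out((R_xlen_t)n_rep * n * 3);
  for (R_xlen_t k = 0; k < (R_xlen_t)n_rep * n * 3; ++k) fr_out[k] = frames[k];
  fr_out.attr("dim") = IntegerVector::create(n, 3, n_rep);

  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i) {
    xf(i, 0) = x[i].x; xf(i, 1) = x[i].y; xf(i, 2) = x[i].z;
    vf(i, 0) = v[i].x; vf(i, 1) = v[i].y; vf(i, 2) = v[i].z;
  }
  return List::create(
    _["frames"] = fr_out,
    _["time"] = wrap(times),
    _["extension"] = wrap(exts),
    _["force"] = wrap(pfs),
    _["potential"] = wrap(pes),
    _["kinetic"] = wrap(kes),
    _["x_final"] = xf,
    _["v_final"] = vf);
}
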