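// Compiled core: pair energies/forces with minimum-image convention,
// Shrake-Rupley SASA, a BAOAB Langevin integrator with a deterministic
// counter-free RNG, and chain-contact detection for cluster analysis.
//
// Units throughout: nm, kJ/mol, ps, amu, elementary charge.
// kB = 0.0083144626 kJ mol^-1 K^-1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_set>

using namespace Rcpp;

static const double KB = 0.0083144626181532;

// ---------------------------------------------------------------------------
// deterministic RNG: splitmix64 -> uniforms -> Box-Muller normals
struct SplitMix {
  uint64_t s;
  bool have_spare = false;
  double spare = 0.0;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { // in (0,1)
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0) +
           0.5 / 9007199254740992.0;
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a); have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
struct PairKey {
  static inline long long key(int i, int j, int n) {
    if (i > j) std::swap(i, j);
    return (long long)i * n + j;
  }
};

struct System {
  int n;
  std::vector<double> x, y, z;       // coordinates
  double bx, by, bz;                 // box edges; <=0 => non-periodic
  bool periodic;
  std::vector<int> type;             // 0-based type index
  std::vector<double> xi;            // per-bead interaction scale
  // type-pair tables (K x K, column-major as from R)
  NumericMatrix sigma, epstot, elec;
  int K;
  double cutoff, kappa;
  bool xi_scales_elec;
  // bonded terms
  std::vector<int> b_i, b_j; std::vector<double> b_l0; double kbond;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_kf;
  std::vector<int> e_i, e_j; std::vector<double> e_r0; double kenm;
  std::unordered_set<long long> excl;

  void mindist(int i, int j, double &dx, double &dy, double &dz) const {
    dx = x[i] - x[j]; dy = y[i] - y[j]; dz = z[i] - z[j];
    if (periodic) {
      dx -= bx * std::nearbyint(dx / bx);
      dy -= by * std::nearbyint(dy / by);
      dz -= bz * std::nearbyint(dz / bz);
    }
  }
};

static System build_system(NumericMatrix coords, NumericVector box,
                           IntegerVector type, NumericVector xi,
                           NumericMatrix sigma, NumericMatrix epstot,
                           NumericMatrix elec, double cutoff, double kappa,
                           bool xi_scales_elec,
                           IntegerMatrix bonds, NumericVector bond_l0,
                           double kbond,
                           IntegerMatrix angles, NumericVector angle_k,
                           IntegerMatrix enm, NumericVector enm_r0,
                           double kenm,
                           IntegerMatrix exclusions) {
  System S;
  S.n = coords.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = coords(i, 0); S.y[i] = coords(i, 1); S.z[i] = coords(i, 2);
  }
  S.bx = box[0]; S.by = box[1]; S.bz = box[2];
  S.periodic = (S.bx > 0 && S.by > 0 && S.bz > 0);
  S.type.assign(type.begin(), type.end());
  S.xi.assign(xi.begin(), xi.end());
  S.sigma = sigma; S.epstot = epstot; S.elec = elec; S.K = sigma.nrow();
  S.cutoff = cutoff; S.kappa = kappa; S.xi_scales_elec = xi_scales_elec;
  int nb = bonds.nrow();
  S.b_i.resize(nb); S.b_j.resize(nb); S.b_l0.resize(nb);
  for (int b = 0; b < nb; ++b) {
    S.b_i[b] = bonds(b, 0); S.b_j[b] = bonds(b, 1); S.b_l0[b] = bond_l0[b];
  }
  S.kbond = kbond;
  int na = angles.nrow();
  S.a_i.resize(na); S.a_j.resize(na); S.a_k.resize(na); S.a_kf.resize(na);
  for (int a = 0; a < na; ++a) {
    S.a_i[a] = angles(a, 0); S.a_j[a] = angles(a, 1); S.a_k[a] = angles(a, 2);
    S.a_kf[a] = angle_k[a];
  }
  int ne = enm.nrow();
  S.e_i.resize(ne); S.e_j.resize(ne); S.e_r0.resize(ne);
  for (int e = 0; e < ne; ++e) {
    S.e_i[e] = enm(e, 0); S.e_j[e] = enm(e, 1); S.e_r0[e] = enm_r0[e];
  }
  S.kenm = kenm;
  for (int e = 0; e < exclusions.nrow(); ++e)
    S.excl.insert(PairKey::key(exclusions(e, 0), exclusions(e, 1), S.n));
  return S;
}

struct Energies {
  double bond = 0, angle = 0, enm = 0, sr = 0, el = 0;
  double total() const { return bond + angle + enm + sr + el; }
};

// bonded terms on raw (unwrapped) coordinates
static void bonded_forces(const System &S, Energies &E,
                          std::vector<double> &fx, std::vector<double> &fy,
                          std::vector<double> &fz) {
  for (size_t b = 0; b < S.b_i.size(); ++b) {
    int i = S.b_i[b], j = S.b_j[b];
    double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - S.b_l0[b];
    E.bond += 0.5 * S.kbond * d * d;
    double f = -S.kbond * d / std::max(r, 1e-12);
    fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
  }
  for (size_t e = 0; e < S.e_i.size(); ++e) {
    int i = S.e_i[e], j = S.e_j[e];
    double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - S.e_r0[e];
    E.enm += 0.5 * S.kenm * d * d;
    double f = -S.kenm * d / std::max(r, 1e-12);
    fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
  }
  const double th0 = M_PI;
  for (size_t a = 0; a < S.a_i.size(); ++a) {
    int i = S.a_i[a], j = S.a_j[a], k = S.a_k[a];
    double ux = S.x[i] - S.x[j], uy = S.y[i] - S.y[j], uz = S.z[i] - S.z[j];
    double vx = S.x[k] - S.x[j], vy = S.y[k] - S.y[j], vz = S.z[k] - S.z[j];
    double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double lv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (lu < 1e-9 || lv < 1e-9) stop("degenerate angle triple (zero-length bond vector)");
    double c = (ux * vx + uy * vy + uz * vz) / (lu * lv);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dth = th - th0;
    E.angle += 0.5 * S.a_kf[a] * dth * dth;
    double s = std::sqrt(std::max(1.0 - c * c, 0.0));
    // g = k (th - th0)/sin(th); as th -> pi this ratio -> -1 (th0 = pi)
    double g;
    if (s < 1e-6) {
      g = -S.a_kf[a];
    } else {
      g = S.a_kf[a] * dth / s;
    }
    double inv_u = 1.0 / lu, inv_v = 1.0 / lv;
    // F_i = g * dcos/dr_i ; dcos/dr_i = (v_hat - c*u_hat)/|u|
    double fix = g * (vx * inv_v - c * ux * inv_u) * inv_u;
    double fiy = g * (vy * inv_v - c * uy * inv_u) * inv_u;
    double fiz = g * (vz * inv_v - c * uz * inv_u) * inv_u;
    double fkx = g * (ux * inv_u - c * vx * inv_v) * inv_v;
    double fky = g * (uy * inv_u - c * vy * inv_v) * inv_v;
    double fkz = g * (uz * inv_u - c * vz * inv_v) * inv_v;
    fx[i] += fix; fy[i] += fiy; fz[i] += fiz;
    fx[k] += fkx; fy[k] += fky; fz[k] += fkz;
    fx[j] -= fix + fkx; fy[j] -= fiy + fky; fz[j] -= fiz + fkz;
  }
}

// one nonbonded pair; returns false if beads overlap exactly
static inline bool pair_nonbonded(const System &S, int i, int j,
                                  Energies &E, std::vector<double> &fx,
                                  std::vector<double> &fy,
                                  std::vector<double> &fz) {
  double dx, dy, dz;
  S.mindist(i, j, dx, dy, dz);
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= S.cutoff * S.cutoff) return true;
  if (r2 < 1e-20) return false;
  double r = std::sqrt(r2);
  int ti = S.type[i], tj = S.type[j];
  double sig = S.sigma(ti, tj);
  double et = S.epstot(ti, tj);
  double xij = S.xi[i] * S.xi[j];
  double q = sig / r, q2 = q * q;
  double sr5 = q2 * q2 * q;
  double sr10 = sr5 * sr5;
  E.sr += xij * 4.0 * et * (sr10 - sr5);
  // dU/dr = xij*4*et*(-10 sr10 + 5 sr5)/r ; F = -dU/dr * rhat
  double fmag = xij * 4.0 * et * (10.0 * sr10 - 5.0 * sr5) / r2; // = -dU/dr / r
  double en = S.elec(ti, tj);
  if (en != 0.0) {
    double escale = S.xi_scales_elec ? xij : 1.0;
    double ee = escale * en * std::exp(-r / S.kappa) / r;
    E.el += ee;
    fmag += ee * (1.0 / r + 1.0 / S.kappa) / r;  // -dU/dr / r
  }
  fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
  fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  return true;
}

// ---------------------------------------------------------------------------
// Verlet neighbour list (O(N^2) build, displacement-triggered rebuild)
struct NeighbourList {
  std::vector<int> pi, pj;
  std::vector<double> x0, y0, z0;
  double skin;
  void build(const System &S) {
    pi.clear(); pj.clear();
    double rl = S.cutoff + skin, rl2 = rl * rl;
    for (int i = 0; i < S.n; ++i)
      for (int j = i + 1; j < S.n; ++j) {
        if (S.excl.count(PairKey::key(i, j, S.n))) continue;
        double dx, dy, dz;
        S.mindist(i, j, dx, dy, dz);
        if (dx * dx + dy * dy + dz * dz < rl2) { pi.push_back(i); pj.push_back(j); }
      }
    x0 = S.x; y0 = S.y; z0 = S.z;
  }
  bool stale(const System &S) const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < S.n; ++i) {
      double dx = S.x[i] - x0[i], dy = S.y[i] - y0[i], dz = S.z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

static Energies all_forces(const System &S, const NeighbourList *nl,
                           std::vector<double> &fx, std::vector<double> &fy,
                           std::vector<double> &fz) {
  Energies E;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  bonded_forces(S, E, fx, fy, fz);
  if (nl) {
    for (size_t p = 0; p < nl->pi.size(); ++p)
      if (!pair_nonbonded(S, nl->pi[p], nl->pj[p], E, fx, fy, fz))
        stop("overlapping beads (r = 0) in nonbonded pair");
  } else {
    for (int i = 0; i < S.n; ++i)
      for (int j = i + 1; j < S.n; ++j) {
        if (S.excl.count(PairKey::key(i, j, S.n))) continue;
        if (!pair_nonbonded(S, i, j, E, fx, fy, fz))
          stop("overlapping beads (r = 0) in nonbonded pair");
      }
  }
  return E;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, NumericVector box,
                       IntegerVector type, NumericVector xi,
                       NumericMatrix sigma, NumericMatrix epstot,
                       NumericMatrix elec, double cutoff, double kappa,
                       bool xi_scales_elec,
                       IntegerMatrix bonds, NumericVector bond_l0,
                       double kbond, IntegerMatrix angles,
                       NumericVector angle_k, IntegerMatrix enm,
                       NumericVector enm_r0, double kenm,
                       IntegerMatrix exclusions, bool use_neighbour_list) {
  System S = build_system(coords, box, type, xi, sigma, epstot, elec, cutoff,
                          kappa, xi_scales_elec, bonds, bond_l0, kbond,
                          angles, angle_k, enm, enm_r0, kenm, exclusions);
  std::vector<double> fx(S.n), fy(S.n), fz(S.n);
  Energies E;
  if (use_neighbour_list) {
    NeighbourList nl; nl.skin = 0.3; nl.build(S);
    E = all_forces(S, &nl, fx, fy, fz);
  } else {
    E = all_forces(S, nullptr, fx, fy, fz);
  }
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i) { F(i,0)=fx[i]; F(i,1)=fy[i]; F(i,2)=fz[i]; }
  return List::create(_["bond"] = E.bond, _["angle"] = E.angle,
                      _["enm"] = E.enm, _["short_range"] = E.sr,
                      _["electrostatic"] = E.el, _["total"] = E.total(),
                      _["forces"] = F);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords, NumericMatrix vels,
                      NumericVector mass, NumericVector box,
                      IntegerVector type, NumericVector xi,
                      NumericMatrix sigma, NumericMatrix epstot,
                      NumericMatrix elec, double cutoff, double kappa,
                      bool xi_scales_elec,
                      IntegerMatrix bonds, NumericVector bond_l0,
                      double kbond, IntegerMatrix angles,
                      NumericVector angle_k, IntegerMatrix enm,
                      NumericVector enm_r0, double kenm,
                      IntegerMatrix exclusions,
                      double dt, double gamma, double temperature,
                      int nsteps, int report_interval, double seed,
                      bool store_frames) {
  System S = build_system(coords, box, type, xi, sigma, epstot, elec, cutoff,
                          kappa, xi_scales_elec, bonds, bond_l0, kbond,
                          angles, angle_k, enm, enm_r0, kenm, exclusions);
  int n = S.n;
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) { vx[i]=vels(i,0); vy[i]=vels(i,1); vz[i]=vels(i,2); }
  std::vector<double> fx(n), fy(n), fz(n);
  NeighbourList nl; nl.skin = 0.3; nl.build(S);
  Energies E = all_forces(S, &nl, fx, fy, fz);
  SplitMix rng((uint64_t)seed);
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  double kT = KB * temperature;
  int nreports = (report_interval > 0) ? nsteps / report_interval : 0;
  NumericMatrix scal(nreports, 8); // step time T Ebond Eang Eenm Esr Eel
  std::vector<NumericMatrix> frames;
  int rep = 0;
  for (int step = 1; step <= nsteps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      double im = dt * 0.5 / mass[i];
      vx[i] += im * fx[i]; vy[i] += im * fy[i]; vz[i] += im * fz[i];
    }
    // A
    for (int i = 0; i < n; ++i) {
      S.x[i] += 0.5 * dt * vx[i]; S.y[i] += 0.5 * dt * vy[i];
      S.z[i] += 0.5 * dt * vz[i];
    }
    // O
    if (gamma > 0 && temperature >= 0) {
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(kT / mass[i]);
        vx[i] = c1 * vx[i] + c2 * sd * rng.norm();
        vy[i] = c1 * vy[i] + c2 * sd * rng.norm();
        vz[i] = c1 * vz[i] + c2 * sd * rng.norm();
      }
    }
    // A
    for (int i = 0; i < n; ++i) {
      S.x[i] += 0.5 * dt * vx[i]; S.y[i] += 0.5 * dt * vy[i];
      S.z[i] += 0.5 * dt * vz[i];
    }
    if (nl.stale(S)) nl.build(S);
    E = all_forces(S, &nl, fx, fy, fz);
    // B
    for (int i = 0; i < n; ++i) {
      double im = dt * 0.5 / mass[i];
      vx[i] += im * fx[i]; vy[i] += im * fy[i]; vz[i] += im * fz[i];
    }
    if (report_interval > 0 && step % report_interval == 0 && rep < nreports) {
      double ke = 0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * mass[i] * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
      double Tinst = 2.0 * ke / (3.0 * n * KB);
      double tot = E.total();
      if (!std::isfinite(tot))
        stop("numerical blow-up: non-finite energy at step %d", step);
      scal(rep,0)=step; scal(rep,1)=step*dt; scal(rep,2)=Tinst;
      scal(rep,3)=E.bond; scal(rep,4)=E.angle; scal(rep,5)=E.enm;
      scal(rep,6)=E.sr; scal(rep,7)=E.el;
      if (store_frames) {
        NumericMatrix fr(n, 3);
        for (int i = 0; i < n; ++i) { fr(i,0)=S.x[i]; fr(i,1)=S.y[i]; fr(i,2)=S.z[i]; }
        frames.push_back(fr);
      }
      ++rep;
    }
  }
  NumericMatrix X(n, 3), V(n, 3);
  for (int i = 0; i < n; ++i) {
    X(i,0)=S.x[i]; X(i,1)=S.y[i]; X(i,2)=S.z[i];
    V(i,0)=vx[i]; V(i,1)=vy[i]; V(i,2)=vz[i];
  }
  List frl(frames.size());
  for (size_t f = 0; f < frames.size(); ++f) frl[f] = frames[f];
  return List::create(_["coords"] = X, _["velocities"] = V,
                      _["scalars"] = scal, _["frames"] = frl);
}

// ---------------------------------------------------------------------------
// Shrake-Rupley SASA on spheres (radii already include no probe; probe added
// here). Deterministic Fibonacci sphere point set.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, int npoints) {
  int n = coords.nrow();
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / npoints;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = ga * k;
    px[k] = rk * std::cos(th); py[k] = rk * std::sin(th); pz[k] = zk;
  }
  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    double Ri = radii[i] + probe;
    // neighbours that can occlude sphere i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j,0)-coords(i,0), dy = coords(j,1)-coords(i,1),
             dz = coords(j,2)-coords(i,2);
      double rj = radii[j] + probe;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < (Ri + rj) * (Ri + rj)) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double qx = coords(i,0) + Ri * px[k];
      double qy = coords(i,1) + Ri * py[k];
      double qz = coords(i,2) + Ri * pz[k];
      bool buried = false;
      for (int m = 0; m < (int)nb.size(); ++m) {
        int j = nb[m];
        double rj = radii[j] + probe;
        double dx = qx - coords(j,0), dy = qy - coords(j,1), dz = qz - coords(j,2);
        if (dx*dx + dy*dy + dz*dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / npoints;
  }
  return area;
}

// ---------------------------------------------------------------------------
// Chain-contact adjacency: chains are in contact when any inter-chain bead
// pair is closer than cutoff (minimum image).
// [[Rcpp::export]]
LogicalMatrix cpp_chain_contacts(NumericMatrix coords, NumericVector box,
                                 IntegerVector chain, double cutoff) {
  int n = coords.nrow();
  int nc = 0;
  for (int i = 0; i < n; ++i) nc = std::max(nc, chain[i] + 1);
  LogicalMatrix M(nc, nc);
  bool periodic = box[0] > 0 && box[1] > 0 && box[2] > 0;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (chain[i] == chain[j]) continue;
      if (M(chain[i], chain[j])) continue;
      double dx = coords(i,0)-coords(j,0), dy = coords(i,1)-coords(j,1),
             dz = coords(i,2)-coords(j,2);
      if (periodic) {
        dx -= box[0] * std::nearbyint(dx / box[0]);
        dy -= box[1] * std::nearbyint(dy / box[1]);
        dz -= box[2] * std::nearbyint(dz / box[2]);
      }
      if (dx*dx + dy*dy + dz*dz < c2) {
        M(chain[i], chain[j]) = true; M(chain[j], chain[i]) = true;
      }
    }
  for (int c = 0; c < nc; ++c) M(c, c) = true;
  return M;
}
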