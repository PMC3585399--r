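// Molecular-mechanics core for small ion-ligand droplet systems.
//
// Units: length Angstrom, energy kcal/mol, mass amu, time fs, charge e.
// All pair interactions are switched between `ron` and `cutoff`; alchemically
// scaled pairs use a shifted-distance softcore so that appearing/disappearing
// atoms never produce a singularity at any lambda < 1.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
#include <random>
#include <algorithm>

using namespace Rcpp;

static const double COUL_CONST = 332.0637;     // kcal*A/(mol*e^2)
static const double KB = 0.0019872041;         // kcal/mol/K
static const double FCONV = 4.184e-4;          // (kcal/mol/A)/amu -> A/fs^2

// ---------------------------------------------------------------------------
// deterministic RNG (mt19937_64 + Box-Muller, no library distributions so the
// stream is identical on every platform)
struct Rng {
  std::mt19937_64 gen;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {
    // 53-bit uniform in (0,1)
    return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
struct Pair {
  int i, j;
  int type;       // 0 plain, 1 scales with (1-lambda), 2 scales with lambda,
                  // 3 ion-morph pair (linear parameter interpolation)
  double qq;      // COUL_CONST * qi * qj
  double epsA, sig2A, epsB, sig2B; // for type 3; type 0/1/2 use epsA/sig2A
  double sigA, sigB;               // precomputed sqrt of sig2A/sig2B
};

struct Bond { int i, j; double r0, k; };
struct Angle { int i, j, k; double th0, ka; };

struct EnergyAcc {
  double coulomb = 0, lj = 0, bonded = 0, wall = 0, anchor = 0;
  double total() const { return coulomb + lj + bonded + wall + anchor; }
};

struct Engine {
  int natom;
  std::vector<double> charge, mass;
  std::vector<int> fixed;           // 1 = immobile (the central ion)
  std::vector<Pair> pairs;
  std::vector<Bond> bonds;
  std::vector<Angle> angles;
  // restraints
  std::vector<int> wall_idx;
  double wall_radius = 3.5, wall_k = 100.0;
  std::vector<int> anchor_idx;
  std::vector<double> anchor_pos;   // 3*m
  std::vector<double> anchor_kf, anchor_kf2;
  int alch_mode = 0;                // 0 none, 1 dual-set, 2 ion-morph, 3 kf-interp
  // nonbonded params
  double rc2, ron2, swdenom, shift;

  explicit Engine(const List& sys) {
    NumericVector q = sys["charge"], eps = sys["eps"], sig = sys["sigma"],
                  m = sys["mass"];
    IntegerVector fx = sys["fixed"], grp = sys["group"];
    natom = q.size();
    charge.assign(q.begin(), q.end());
    mass.assign(m.begin(), m.end());
    fixed.assign(fx.begin(), fx.end());
    List nb = sys["nb"];
    double rc = as<double>(nb["cutoff"]), ron = as<double>(nb["switch_start"]);
    shift = as<double>(nb["softcore_shift"]);
    rc2 = rc * rc; ron2 = ron * ron;
    swdenom = 1.0 / ((rc2 - ron2) * (rc2 - ron2) * (rc2 - ron2));
    alch_mode = as<int>(sys["alch_mode"]);

    // exclusions -> boolean lookup
    IntegerMatrix excl = sys["excl"];
    std::vector<char> ex((size_t)natom * natom, 0);
    for (int r = 0; r < excl.nrow(); ++r) {
      int a = excl(r, 0), b = excl(r, 1);
      ex[(size_t)a * natom + b] = ex[(size_t)b * natom + a] = 1;
    }

    int ion_idx = -1;
    double iepsA = 0, isigA = 0, iepsB = 0, isigB = 0;
    if (alch_mode == 2) {
      ion_idx = as<int>(sys["ion_idx"]);
      iepsA = as<double>(sys["ion_epsA"]); isigA = as<double>(sys["ion_sigmaA"]);
      iepsB = as<double>(sys["ion_epsB"]); isigB = as<double>(sys["ion_sigmaB"]);
    }

    for (int i = 0; i < natom; ++i) {
      for (int j = i + 1; j < natom; ++j) {
        if (ex[(size_t)i * natom + j]) continue;
        int gi = grp[i], gj = grp[j];
        if ((gi == 1 && gj == 2) || (gi == 2 && gj == 1)) continue; // dual sets never see each other
        Pair p;
        p.i = i; p.j = j;
        p.qq = COUL_CONST * charge[i] * charge[j];
        if (alch_mode == 2 && (i == ion_idx || j == ion_idx)) {
          int o = (i == ion_idx) ? j : i;
          p.type = 3;
          double sA = 0.5 * (isigA + sig[o]), sB = 0.5 * (isigB + sig[o]);
          p.epsA = std::sqrt(iepsA * eps[o]); p.sig2A = sA * sA;
          p.epsB = std::sqrt(iepsB * eps[o]); p.sig2B = sB * sB;
          p.sigA = sA; p.sigB = sB;
        } else {
          // group scaling only exists in dual-set morphs
          p.type = (alch_mode != 1) ? 0 :
                   (gi == 1 || gj == 1) ? 1 : (gi == 2 || gj == 2) ? 2 : 0;
          double s = 0.5 * (sig[i] + sig[j]);
          p.epsA = std::sqrt(eps[i] * eps[j]); p.sig2A = s * s;
          p.epsB = p.epsA; p.sig2B = p.sig2A;
          p.sigA = s; p.sigB = s;
        }
        if (p.qq == 0.0 && p.epsA == 0.0 && p.epsB == 0.0) continue;
        pairs.push_back(p);
      }
    }

    NumericMatrix bm = sys["bonds"];
    for (int r = 0; r < bm.nrow(); ++r)
      bonds.push_back({(int)bm(r, 0), (int)bm(r, 1), bm(r, 2), bm(r, 3)});
    NumericMatrix am = sys["angles"];
    for (int r = 0; r < am.nrow(); ++r)
      angles.push_back({(int)am(r, 0), (int)am(r, 1), (int)am(r, 2), am(r, 3), am(r, 4)});

    IntegerVector wi = sys["wall_idx"];
    wall_idx.assign(wi.begin(), wi.end());
    wall_radius = as<double>(sys["wall_radius"]);
    wall_k = as<double>(sys["wall_k"]);
    IntegerVector ai = sys["anchor_idx"];
    anchor_idx.assign(ai.begin(), ai.end());
    NumericMatrix ap = sys["anchor_pos"];
    anchor_pos.resize(3 * anchor_idx.size());
    for (size_t r = 0; r < anchor_idx.size(); ++r)
      for (int d = 0; d < 3; ++d) anchor_pos[3 * r + d] = ap(r, d);
    NumericVector kf = sys["anchor_kf"];
    anchor_kf.assign(kf.begin(), kf.end());
    if (sys.containsElementNamed("anchor_kf2") && !Rf_isNull(sys["anchor_kf2"])) {
      NumericVector kf2 = sys["anchor_kf2"];
      anchor_kf2.assign(kf2.begin(), kf2.end());
    } else {
      anchor_kf2 = anchor_kf;
    }
  }

  // switching function and derivative wrt r2
  inline double sw(double r2, double& dswdr2) const {
    if (r2 <= ron2) { dswdr2 = 0.0; return 1.0; }
    double a = rc2 - r2;
    double s = a * a * (rc2 + 2.0 * r2 - 3.0 * ron2) * swdenom;
    // dS/dr = 12 r (rc2-r2)(ron2-r2)/denom  =>  dS/dr2 = 6 (rc2-r2)(ron2-r2)/denom
    dswdr2 = 6.0 * a * (ron2 - r2) * swdenom;
    return s;
  }

  // full energy (+forces if f != nullptr) at coordinates x (3*natom), state lambda
  EnergyAcc eval(const double* x, double lambda, double* f) const {
    EnergyAcc e;
    if (f) std::fill(f, f + 3 * natom, 0.0);

    for (const Pair& p : pairs) {
      double s = 1.0, epsv = p.epsA, sig2 = p.sig2A;
      if (p.type == 1) { s = 1.0 - lambda; if (s <= 0.0) continue; }
      else if (p.type == 2) { s = lambda; if (s <= 0.0) continue; }
      else if (p.type == 3) {
        // linear interpolation of the ion's LJ parameters (full core at all lambda)
        double sv = (1.0 - lambda) * p.sigA + lambda * p.sigB;
        sig2 = sv * sv;
        epsv = (1.0 - lambda) * p.epsA + lambda * p.epsB;
      }
      double dx = x[3 * p.i] - x[3 * p.j];
      double dy = x[3 * p.i + 1] - x[3 * p.j + 1];
      double dz = x[3 * p.i + 2] - x[3 * p.j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double dswdr2 = 0.0, S = 1.0;
      if (r2 > ron2) S = sw(r2, dswdr2);
      double rs2 = (p.type == 1 || p.type == 2)
                     ? r2 + shift * (1.0 - s) * sig2 : r2;
      double ulj = 0.0, dulj = 0.0;
      if (epsv != 0.0) {
        double t = sig2 / rs2, u = t * t * t;
        double se4 = s * 4.0 * epsv;
        ulj = se4 * (u * u - u);
        if (f) dulj = se4 * (2.0 * u - 1.0) * (-3.0 * u / rs2);
      }
      double uc = 0.0, duc = 0.0;
      if (p.qq != 0.0) {
        uc = s * p.qq / std::sqrt(rs2);
        if (f) duc = -0.5 * uc / rs2;
      }
      e.lj += ulj * S;
      e.coulomb += uc * S;
      if (f) {
        double dtot = (dulj + duc) * S + (ulj + uc) * dswdr2;  // dU/dr2
        double g = 2.0 * dtot;
        f[3 * p.i] -= g * dx; f[3 * p.i + 1] -= g * dy; f[3 * p.i + 2] -= g * dz;
        f[3 * p.j] += g * dx; f[3 * p.j + 1] += g * dy; f[3 * p.j + 2] += g * dz;
      }
    }

    for (const Bond& b : bonds) {
      double dx = x[3 * b.i] - x[3 * b.j];
      double dy = x[3 * b.i + 1] - x[3 * b.j + 1];
      double dz = x[3 * b.i + 2] - x[3 * b.j + 2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dd = d - b.r0;
      e.bonded += 0.5 * b.k * dd * dd;
      if (f && d > 1e-12) {
        double g = b.k * dd / d;
        f[3 * b.i] -= g * dx; f[3 * b.i + 1] -= g * dy; f[3 * b.i + 2] -= g * dz;
        f[3 * b.j] += g * dx; f[3 * b.j + 1] += g * dy; f[3 * b.j + 2] += g * dz;
      }
    }

    for (const Angle& a : angles) {
      double rij[3], rkj[3];
      for (int d = 0; d < 3; ++d) {
        rij[d] = x[3 * a.i + d] - x[3 * a.j + d];
        rkj[d] = x[3 * a.k + d] - x[3 * a.j + d];
      }
      double nij = std::sqrt(rij[0]*rij[0] + rij[1]*rij[1] + rij[2]*rij[2]);
      double nkj = std::sqrt(rkj[0]*rkj[0] + rkj[1]*rkj[1] + rkj[2]*rkj[2]);
      double c = (rij[0]*rkj[0] + rij[1]*rkj[1] + rij[2]*rkj[2]) / (nij * nkj);
      c = std::max(-1.0, std::min(1.0, c));
      double th = std::acos(c);
      double dth = th - a.th0;
      e.bonded += 0.5 * a.ka * dth * dth;
      if (f) {
        double st = std::sqrt(std::max(1.0 - c * c, 1e-12));
        double coeff = a.ka * dth / st;
        for (int d = 0; d < 3; ++d) {
          double uij = rij[d] / nij, ukj = rkj[d] / nkj;
          double fi = coeff * (ukj - c * uij) / nij;
          double fk = coeff * (uij - c * ukj) / nkj;
          f[3 * a.i + d] += fi;
          f[3 * a.k + d] += fk;
          f[3 * a.j + d] -= fi + fk;
        }
      }
    }

    for (int idx : wall_idx) {
      double dx = x[3 * idx], dy = x[3 * idx + 1], dz = x[3 * idx + 2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > wall_radius) {
        double dd = d - wall_radius;
        e.wall += 0.5 * wall_k * dd * dd;
        if (f && d > 1e-12) {
          double g = wall_k * dd / d;
          f[3 * idx] -= g * dx; f[3 * idx + 1] -= g * dy; f[3 * idx + 2] -= g * dz;
        }
      }
    }

    for (size_t r = 0; r < anchor_idx.size(); ++r) {
      double kf = anchor_kf[r];
      if (alch_mode == 3) kf = (1.0 - lambda) * anchor_kf[r] + lambda * anchor_kf2[r];
      if (kf <= 0.0) continue;
      int idx = anchor_idx[r];
      double dx = x[3 * idx] - anchor_pos[3 * r];
      double dy = x[3 * idx + 1] - anchor_pos[3 * r + 1];
      double dz = x[3 * idx + 2] - anchor_pos[3 * r + 2];
      e.anchor += 0.5 * kf * (dx * dx + dy * dy + dz * dz);
      if (f) {
        f[3 * idx] -= kf * dx; f[3 * idx + 1] -= kf * dy; f[3 * idx + 2] -= kf * dz;
      }
    }
    return e;
  }
};

static NumericVector acc_to_vec(const EnergyAcc& e) {
  NumericVector out = NumericVector::create(
    _["coulomb"] = e.coulomb, _["lj"] = e.lj, _["bonded"] = e.bonded,
    _["wall_restraint"] = e.wall, _["anchor_restraint"] = e.anchor,
    _["total"] = e.total());
  return out;
}

// [[Rcpp::export]]
NumericVector eng_energy(List sys, NumericMatrix coords, double lambda) {
  Engine eng(sys);
  std::vector<double> x(3 * eng.natom);
  for (int i = 0; i < eng.natom; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  return acc_to_vec(eng.eval(x.data(), lambda, nullptr));
}

// [[Rcpp::export]]
NumericMatrix eng_forces(List sys, NumericMatrix coords, double lambda) {
  Engine eng(sys);
  std::vector<double> x(3 * eng.natom), f(3 * eng.natom);
  for (int i = 0; i < eng.natom; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  eng.eval(x.data(), lambda, f.data());
  NumericMatrix out(eng.natom, 3);
  for (int i = 0; i < eng.natom; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = f[3 * i + d];
  return out;
}

// BAOAB Langevin integrator; the central ion (fixed flag) never moves.
// [[Rcpp::export]]
List eng_dynamics(List sys, NumericMatrix coords, double lambda, int nsteps,
                  double dt, double temperature, double friction, int seed,
                  int save_interval) {
  Engine eng(sys);
  int N = eng.natom;
  std::vector<double> x(3 * N), v(3 * N, 0.0), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);

  Rng rng((uint64_t)seed * 2654435761u + 17u);
  int nmobile = 0;
  for (int i = 0; i < N; ++i) if (!eng.fixed[i]) ++nmobile;
  // Maxwell-Boltzmann initial velocities
  for (int i = 0; i < N; ++i) {
    if (eng.fixed[i]) continue;
    double sdv = std::sqrt(KB * temperature * FCONV / eng.mass[i]);
    for (int d = 0; d < 3; ++d) v[3 * i + d] = sdv * rng.norm();
  }

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  int nsave = nsteps / save_interval + 1;
  NumericVector frames(Dimension(nsave, N, 3));
  NumericMatrix eser(nsave, 8);
  colnames(eser) = CharacterVector::create("step", "coulomb", "lj", "bonded",
                                           "wall_restraint", "anchor_restraint",
                                           "total", "tkin");
  int isave = 0;
  EnergyAcc e0 = eng.eval(x.data(), lambda, f.data());
  auto record = [&](int step, const EnergyAcc& e) {
    double ke = 0.0;
    for (int i = 0; i < N; ++i) {
      if (eng.fixed[i]) continue;
      ke += 0.5 * eng.mass[i] *
            (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]) / FCONV;
    }
    double tk = (nmobile > 0) ? 2.0 * ke / (3.0 * nmobile * KB) : 0.0;
    eser(isave, 0) = step;
    eser(isave, 1) = e.coulomb; eser(isave, 2) = e.lj; eser(isave, 3) = e.bonded;
    eser(isave, 4) = e.wall; eser(isave, 5) = e.anchor; eser(isave, 6) = e.total();
    eser(isave, 7) = tk;
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        frames[isave + (R_xlen_t)nsave * (i + (R_xlen_t)N * d)] = x[3 * i + d];
    ++isave;
  };
  if (!std::isfinite(e0.total()))
    stop("non-finite energy at step 0");
  record(0, e0);

  for (int step = 1; step <= nsteps; ++step) {
    // B
    for (int i = 0; i < N; ++i) {
      if (eng.fixed[i]) continue;
      double a = 0.5 * dt * FCONV / eng.mass[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += a * f[3 * i + d];
    }
    // A
    for (int i = 0; i < N; ++i) {
      if (eng.fixed[i]) continue;
      for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    }
    // O
    for (int i = 0; i < N; ++i) {
      if (eng.fixed[i]) continue;
      double sdv = std::sqrt(KB * temperature * FCONV / eng.mass[i]);
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] = c1 * v[3 * i + d] + c2 * sdv * rng.norm();
    }
    // A
    for (int i = 0; i < N; ++i) {
      if (eng.fixed[i]) continue;
      for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    }
    // B
    EnergyAcc e = eng.eval(x.data(), lambda, f.data());
    for (int i = 0; i < N; ++i) {
      if (eng.fixed[i]) continue;
      double a = 0.5 * dt * FCONV / eng.mass[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += a * f[3 * i + d];
    }
    if (step % save_interval == 0) {
      double tot = e.total();
      if (!std::isfinite(tot) || std::fabs(tot) > 1e6)
        stop("dynamics instability at step %d (|E| = %g kcal/mol)", step, tot);
      record(step, e);
    }
  }

  NumericMatrix fin(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) fin(i, d) = x[3 * i + d];
  return List::create(_["frames"] = frames, _["energies"] = eser,
                      _["final_coords"] = fin, _["nsave"] = nsave);
}

// Re-evaluate total potential energy of saved frames at a set of lambda values.
// [[Rcpp::export]]
NumericMatrix eng_cross(List sys, NumericVector frames, NumericVector lambdas) {
  Engine eng(sys);
  IntegerVector dim = frames.attr("dim");
  int nf = dim[0], N = dim[1];
  if (N != eng.natom) stop("frame atom count does not match system");
  NumericMatrix out(nf, lambdas.size());
  std::vector<double> x(3 * N);
  for (int fidx = 0; fidx < nf; ++fidx) {
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        x[3 * i + d] = frames[fidx + (R_xlen_t)nf * (i + (R_xlen_t)N * d)];
    for (int l = 0; l < lambdas.size(); ++l)
      out(fidx, l) = eng.eval(x.data(), lambdas[l], nullptr).total();
  }
  return out;
}

// Adaptive-step steepest descent; energy never increases across accepted steps.
// [[Rcpp::export]]
List eng_minimise(List sys, NumericMatrix coords, double lambda, int max_steps,
                  double tol) {
  Engine eng(sys);
  int N = eng.natom;
  std::vector<double> x(3 * N), f(3 * N), xtry(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  double e = eng.eval(x.data(), lambda, f.data()).total();
  if (!std::isfinite(e)) stop("non-finite energy at start of minimisation");
  double step = 0.02;
  double fmax = 0.0;
  int it = 0;
  bool converged = false;
  for (; it < max_steps; ++it) {
    fmax = 0.0;
    for (int i = 0; i < N; ++i) {
      if (eng.fixed[i]) continue;
      for (int d = 0; d < 3; ++d) fmax = std::max(fmax, std::fabs(f[3 * i + d]));
    }
    if (fmax <= tol) { converged = true; break; }
    double scale = step / std::max(fmax, 1e-12);
    for (int i = 0; i < N; ++i) {
      if (eng.fixed[i]) { for (int d = 0; d < 3; ++d) xtry[3*i+d] = x[3*i+d]; continue; }
      for (int d = 0; d < 3; ++d) xtry[3 * i + d] = x[3 * i + d] + scale * f[3 * i + d];
    }
    double etry = eng.eval(xtry.data(), lambda, nullptr).total();
    if (!std::isfinite(etry)) stop("non-finite energy during minimisation");
    if (etry <= e) {
      x = xtry;
      e = etry;
      eng.eval(x.data(), lambda, f.data());
      step = std::min(step * 1.2, 0.5);
    } else {
      step *= 0.5;
      if (step < 1e-10) { break; }
    }
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3 * i + d];
  return List::create(_["coords"] = out, _["energy"] = e, _["converged"] = converged,
                      _["iterations"] = it, _["max_force"] = fmax);
}

// Union-of-spheres occupancy grid over trajectory frames.
// mode 0: cumulative (voxel counts if ever occupied); mode 1: frame fraction.
// [[Rcpp::export]]
List eng_occupancy(NumericVector frames, IntegerVector sel, NumericVector radii,
                   double spacing, double isovalue, int mode) {
  IntegerVector dim = frames.attr("dim");
  int nf = dim[0], N = dim[1];
  if (sel.size() == 0) stop("empty atom selection");
  if (nf == 0)
    return List::create(_["volume"] = 0.0, _["nvoxel"] = 0, _["nframes"] = 0);
  double rmax = 0.0;
  for (int s = 0; s < sel.size(); ++s) rmax = std::max(rmax, radii[s]);
  double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
  for (int fidx = 0; fidx < nf; ++fidx)
    for (int s = 0; s < sel.size(); ++s) {
      int a = sel[s];
      for (int d = 0; d < 3; ++d) {
        double c = frames[fidx + (R_xlen_t)nf * (a + (R_xlen_t)N * d)];
        lo[d] = std::min(lo[d], c); hi[d] = std::max(hi[d], c);
      }
    }
  int n[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] -= rmax + spacing; hi[d] += rmax + spacing;
    n[d] = (int)std::ceil((hi[d] - lo[d]) / spacing) + 1;
  }
  size_t nvox = (size_t)n[0] * n[1] * n[2];
  std::vector<uint16_t> count(nvox, 0);
  std::vector<char> hit(nvox, 0);
  for (int fidx = 0; fidx < nf; ++fidx) {
    std::fill(hit.begin(), hit.end(), 0);
    for (int s = 0; s < sel.size(); ++s) {
      int a = sel[s];
      double cx = frames[fidx + (R_xlen_t)nf * (a + (R_xlen_t)N * 0)];
      double cy = frames[fidx + (R_xlen_t)nf * (a + (R_xlen_t)N * 1)];
      double cz = frames[fidx + (R_xlen_t)nf * (a + (R_xlen_t)N * 2)];
      double r = radii[s], r2 = r * r;
      int i0 = std::max(0, (int)((cx - r - lo[0]) / spacing));
      int i1 = std::min(n[0] - 1, (int)((cx + r - lo[0]) / spacing) + 1);
      int j0 = std::max(0, (int)((cy - r - lo[1]) / spacing));
      int j1 = std::min(n[1] - 1, (int)((cy + r - lo[1]) / spacing) + 1);
      int k0 = std::max(0, (int)((cz - r - lo[2]) / spacing));
      int k1 = std::min(n[2] - 1, (int)((cz + r - lo[2]) / spacing) + 1);
      for (int i = i0; i <= i1; ++i) {
        double dx = lo[0] + i * spacing - cx;
        for (int j = j0; j <= j1; ++j) {
          double dy = lo[1] + j * spacing - cy;
          double dxy2 = dx * dx + dy * dy;
          if (dxy2 > r2) continue;
          for (int k = k0; k <= k1; ++k) {
            double dz = lo[2] + k * spacing - cz;
            if (dxy2 + dz * dz <= r2)
              hit[((size_t)i * n[1] + j) * n[2] + k] = 1;
          }
        }
      }
    }
    for (size_t vx = 0; vx < nvox; ++vx)
      if (hit[vx] && count[vx] < 65535) ++count[vx];
  }
  size_t pass = 0;
  if (mode == 0) {
    for (size_t vx = 0; vx < nvox; ++vx) if (count[vx] > 0) ++pass;
  } else {
    for (size_t vx = 0; vx < nvox; ++vx)
      if ((double)count[vx] / nf >= isovalue) ++pass;
  }
  double vol = (double)pass * spacing * spacing * spacing;
  return List::create(_["volume"] = vol, _["nvoxel"] = (double)pass,
                      _["nframes"] = nf);
}

// Single switched/softcore pair energy (reference form used by the energy model).
// [[Rcpp::export]]
double eng_pair_energy(double qi, double qj, double eps_ij, double sigma_ij,
                       double r, double cutoff, double switch_start,
                       double softcore_shift, double lambda_vdw,
                       double lambda_elec) {
  if (r <= 0.0 && lambda_vdw >= 1.0)
    stop("zero interatomic distance with full van der Waals coupling");
  double r2 = r * r;
  double rc2 = cutoff * cutoff, ron2 = switch_start * switch_start;
  if (r2 >= rc2) return 0.0;
  double S = 1.0;
  if (r2 > ron2) {
    double a = rc2 - r2;
    S = a * a * (rc2 + 2.0 * r2 - 3.0 * ron2) /
        ((rc2 - ron2) * (rc2 - ron2) * (rc2 - ron2));
  }
  double sig2 = sigma_ij * sigma_ij;
  double rs2 = r2 + softcore_shift * (1.0 - lambda_vdw) * sig2;
  double ulj = 0.0;
  if (eps_ij > 0.0 && sig2 > 0.0) {
    double t = sig2 / rs2, u = t * t * t;
    ulj = lambda_vdw * 4.0 * eps_ij * (u * u - u);
  }
  double uc = lambda_elec * COUL_CONST * qi * qj / r;
  return S * (ulj + uc);
}
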