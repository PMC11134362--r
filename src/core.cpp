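// Numerical kernels for the coarse-grained constant-pH / Langevin engine.
//
// Conventions: energies in kBT (kBT == 1), lengths in nm, all masses == 1,
// cubic periodic box with minimum-image distances.  Coordinates are kept
// unwrapped; periodicity enters only through the minimum image.  All
// randomness is drawn from R's RNG stream (set.seed() on the R side makes
// runs bit-for-bit reproducible).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

struct FF {
  double eps;      // WCA well depth [kBT]
  double sigma;    // bead diameter [nm]
  double bond_k;   // harmonic bond constant [kBT/nm^2]
  double bond_r0;  // bond rest length [nm]
  double lB;       // Bjerrum length [nm]
  double kappa;    // inverse Debye length [1/nm]
  double rc;       // electrostatic cutoff [nm]
  bool dh;         // screened (Debye-Hueckel) vs bare Coulomb
  double ushift;   // per-unit-charge-product shift so u_elec(rc) = 0
  double wca_cut2; // (2^{1/6} sigma)^2
};

FF parse_ff(const List& ffl) {
  FF f;
  f.eps = as<double>(ffl["wca_epsilon"]);
  f.sigma = as<double>(ffl["sigma"]);
  f.bond_k = as<double>(ffl["bond_k"]);
  f.bond_r0 = as<double>(ffl["bond_r0"]);
  f.lB = as<double>(ffl["bjerrum_length"]);
  f.kappa = as<double>(ffl["kappa"]);
  f.rc = as<double>(ffl["rcut_elec"]);
  std::string mode = as<std::string>(ffl["electrostatics_mode"]);
  f.dh = (mode != "coulomb_explicit_ions");
  f.ushift = 0.0;
  if (f.lB > 0.0 && f.rc > 0.0)
    f.ushift = f.dh ? f.lB * std::exp(-f.kappa * f.rc) / f.rc : f.lB / f.rc;
  double c = std::pow(2.0, 1.0 / 6.0) * f.sigma;
  f.wca_cut2 = c * c;
  return f;
}

inline double mimg(double d, double L) { return d - L * std::nearbyint(d / L); }

// Raw view of the particle arrays (column-major n_cap x 3 matrices).
struct Sys {
  double *x, *y, *z;
  double *q;
  double L;
};

inline double dist2(const Sys& s, int i, int j,
                    double* dx, double* dy, double* dz) {
  *dx = mimg(s.x[i] - s.x[j], s.L);
  *dy = mimg(s.y[i] - s.y[j], s.L);
  *dz = mimg(s.z[i] - s.z[j], s.L);
  return *dx * *dx + *dy * *dy + *dz * *dz;
}

inline double pair_energy(double r2, double q12, const FF& f) {
  double u = 0.0;
  if (f.eps > 0.0 && r2 < f.wca_cut2) {
    double sr2 = f.sigma * f.sigma / r2;
    double sr6 = sr2 * sr2 * sr2;
    u += 4.0 * f.eps * (sr6 * sr6 - sr6) + f.eps;
  }
  if (q12 != 0.0 && f.lB > 0.0 && r2 < f.rc * f.rc) {
    double r = std::sqrt(r2);
    u += f.dh ? q12 * (f.lB * std::exp(-f.kappa * r) / r - f.ushift)
              : q12 * (f.lB / r - f.ushift);
  }
  return u;
}

double total_energy_raw(const Sys& s, int nact, const IntegerMatrix& bonds,
                        const FF& f) {
  double U = 0.0;
  for (int i = 0; i < nact; ++i) {
    for (int j = i + 1; j < nact; ++j) {
      double dx, dy, dz;
      double r2 = dist2(s, i, j, &dx, &dy, &dz);
      if (r2 < 1e-14) return R_PosInf;
      U += pair_energy(r2, s.q[i] * s.q[j], f);
    }
  }
  // bonded pairs use raw (unwrapped) displacements: bonded neighbours are
  // physically adjacent, and the minimum image would make the spring force
  // discontinuous for transiently stretched bonds
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - f.bond_r0;
    U += 0.5 * f.bond_k * d * d;
  }
  return U;
}

void forces_raw(const Sys& s, int nact, const IntegerMatrix& bonds,
                const FF& f, double* fx, double* fy, double* fz) {
  for (int i = 0; i < nact; ++i) fx[i] = fy[i] = fz[i] = 0.0;
  double rc2 = f.rc * f.rc;
  for (int i = 0; i < nact; ++i) {
    for (int j = i + 1; j < nact; ++j) {
      double dx, dy, dz;
      double r2 = dist2(s, i, j, &dx, &dy, &dz);
      if (r2 < 1e-14) continue;
      double fr = 0.0;
      if (f.eps > 0.0 && r2 < f.wca_cut2) {
        double sr2 = f.sigma * f.sigma / r2;
        double sr6 = sr2 * sr2 * sr2;
        fr += 24.0 * f.eps * (2.0 * sr6 * sr6 - sr6) / r2;
      }
      double q12 = s.q[i] * s.q[j];
      if (q12 != 0.0 && f.lB > 0.0 && r2 < rc2) {
        double r = std::sqrt(r2);
        fr += f.dh
          ? q12 * f.lB * std::exp(-f.kappa * r) * (f.kappa * r + 1.0) / (r2 * r)
          : q12 * f.lB / (r2 * r);
      }
      if (fr != 0.0) {
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
  }
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double fr = -f.bond_k * (r - f.bond_r0) / r;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }
}

// Electrostatic energy per unit charge placed at particle i (site potential
// in the truncated/shifted pair convention).  `skip` excludes one particle.
double site_elec_per_charge(const Sys& s, int nact, int i, const FF& f,
                            int skip) {
  if (f.lB <= 0.0) return 0.0;
  double rc2 = f.rc * f.rc, acc = 0.0;
  for (int j = 0; j < nact; ++j) {
    if (j == i || j == skip || s.q[j] == 0.0) continue;
    double dx, dy, dz;
    double r2 = dist2(s, i, j, &dx, &dy, &dz);
    if (r2 >= rc2) continue;
    double r = std::sqrt(r2);
    acc += f.dh ? s.q[j] * (f.lB * std::exp(-f.kappa * r) / r - f.ushift)
                : s.q[j] * (f.lB / r - f.ushift);
  }
  return acc;
}

// Full (WCA + electrostatic) interaction energy of particle k with all
// other active particles.
double particle_energy(const Sys& s, int nact, int k, const FF& f) {
  double U = 0.0;
  for (int j = 0; j < nact; ++j) {
    if (j == k) continue;
    double dx, dy, dz;
    double r2 = dist2(s, k, j, &dx, &dy, &dz);
    if (r2 < 1e-14) return R_PosInf;
    U += pair_energy(r2, s.q[k] * s.q[j], f);
  }
  return U;
}

// BAOAB splitting of underdamped Langevin dynamics, kBT = 1, m = 1.
// Forces in fx/fy/fz must be current on entry and are current on exit.
void ld_steps(Sys& s, double* vx, double* vy, double* vz, int nact,
              const IntegerMatrix& bonds, const FF& f,
              double dt, double gamma, int nsteps,
              double* fx, double* fy, double* fz) {
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < nact; ++i) {
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
      s.x[i] += 0.5 * dt * vx[i];
      s.y[i] += 0.5 * dt * vy[i];
      s.z[i] += 0.5 * dt * vz[i];
      if (gamma > 0.0) {
        vx[i] = c1 * vx[i] + c2 * norm_rand();
        vy[i] = c1 * vy[i] + c2 * norm_rand();
        vz[i] = c1 * vz[i] + c2 * norm_rand();
      }
      s.x[i] += 0.5 * dt * vx[i];
      s.y[i] += 0.5 * dt * vy[i];
      s.z[i] += 0.5 * dt * vz[i];
    }
    forces_raw(s, nact, bonds, f, fx, fy, fz);
    for (int i = 0; i < nact; ++i) {
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
    }
  }
}

} // namespace

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, NumericVector q,
                        IntegerMatrix bonds, double L, List ffl) {
  FF f = parse_ff(ffl);
  int n = pos.nrow();
  Sys s{REAL(pos), REAL(pos) + n, REAL(pos) + 2 * n, REAL(q), L};
  return total_energy_raw(s, n, bonds, f);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, NumericVector q,
                         IntegerMatrix bonds, double L, List ffl) {
  FF f = parse_ff(ffl);
  int n = pos.nrow();
  Sys s{REAL(pos), REAL(pos) + n, REAL(pos) + 2 * n, REAL(q), L};
  NumericMatrix F(n, 3);
  forces_raw(s, n, bonds, f, REAL(F), REAL(F) + n, REAL(F) + 2 * n);
  return F;
}

// Capped steepest-descent relaxation (removes initial-placement overlaps).
// [[Rcpp::export]]
NumericMatrix cpp_minimize(NumericMatrix pos0, NumericVector q,
                           IntegerMatrix bonds, double L, List ffl,
                           int max_steps, double max_disp, double ftol) {
  FF f = parse_ff(ffl);
  NumericMatrix pos = clone(pos0);
  int n = pos.nrow();
  Sys s{REAL(pos), REAL(pos) + n, REAL(pos) + 2 * n, REAL(q), L};
  std::vector<double> fx(n), fy(n), fz(n);
  double h = max_disp;
  double U = total_energy_raw(s, n, bonds, f);
  for (int step = 0; step < max_steps; ++step) {
    forces_raw(s, n, bonds, f, fx.data(), fy.data(), fz.data());
    double fmax = 0.0;
    for (int i = 0; i < n; ++i) {
      fmax = std::max(fmax, std::fabs(fx[i]));
      fmax = std::max(fmax, std::fabs(fy[i]));
      fmax = std::max(fmax, std::fabs(fz[i]));
    }
    if (fmax < ftol) break;
    double scale = h / fmax;
    std::vector<double> xs(s.x, s.x + n), ys(s.y, s.y + n), zs(s.z, s.z + n);
    for (int i = 0; i < n; ++i) {
      s.x[i] += scale * fx[i];
      s.y[i] += scale * fy[i];
      s.z[i] += scale * fz[i];
    }
    double Unew = total_energy_raw(s, n, bonds, f);
    if (R_finite(U) && Unew > U) {
      std::copy(xs.begin(), xs.end(), s.x);
      std::copy(ys.begin(), ys.end(), s.y);
      std::copy(zs.begin(), zs.end(), s.z);
      h *= 0.5;
      if (h < 1e-8) break;
    } else {
      U = Unew;
      h = std::min(h * 1.1, max_disp);
    }
  }
  return pos;
}

// Coupled constant-pH Monte Carlo + Langevin dynamics driver.
//
// Implicit-ion (Debye-Hueckel) mode: insertions/deletions of neutralizing
// cations are count-only bookkeeping; the move's Delta-U contains only the
// polymer electrostatic change.  Explicit-ion mode: the neutralizing cation
// is an actual particle inserted uniformly at random / deleted at random
// among the cations; pos/vel/q carry spare capacity rows for insertions.
//
// tit_idx0: 0-based indices of titratable beads; bonds0: 0-based pairs.
// Returns recorded frames (one per cycle after warmup) plus per-cycle
// scalars and the final state.
// [[Rcpp::export]]
List cpp_run_cph_ld(NumericMatrix pos0, NumericMatrix vel0, NumericVector q0,
                    IntegerVector tit_idx0, double tit_valence,
                    IntegerMatrix bonds0, double L, List ffl,
                    double dt, double gamma, double pH, double pKa,
                    int moves_per_cycle, int ld_steps_per_cycle,
                    int n_cycles, int warmup_cycles,
                    bool explicit_ions, int n_active0, int n_polymer,
                    int implicit_cations, int implicit_anions,
                    IntegerVector mol_start0, IntegerVector mol_len,
                    int translation_moves_per_cycle) {
  FF f = parse_ff(ffl);
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  NumericVector q = clone(q0);
  int ncap = pos.nrow();
  int nact = explicit_ions ? n_active0 : ncap;
  Sys s{REAL(pos), REAL(pos) + ncap, REAL(pos) + 2 * ncap, REAL(q), L};
  double *vx = REAL(vel), *vy = REAL(vel) + ncap, *vz = REAL(vel) + 2 * ncap;
  std::vector<double> fx(ncap), fy(ncap), fz(ncap);

  int ntit = tit_idx0.size();
  const double ln10 = std::log(10.0);
  long cat = implicit_cations, an = implicit_anions;
  // explicit mode: number of deletable cations among the ion particles
  long ncat_expl = 0;
  if (explicit_ions)
    for (int j = n_polymer; j < nact; ++j)
      if (q[j] > 0.0) ++ncat_expl;

  int n_rec = n_cycles - warmup_cycles;
  if (n_rec < 0) n_rec = 0;
  List frames(n_rec);
  NumericVector rec_alpha(n_rec), rec_epot(n_rec), rec_ekin(n_rec),
      rec_acc(n_rec), rec_cat(n_rec), rec_an(n_rec);
  IntegerVector rec_cycle(n_rec);

  forces_raw(s, nact, bonds0, f, fx.data(), fy.data(), fz.data());

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    // --- constant-pH MC sweep -------------------------------------------
    int attempted = 0, accepted = 0;
    for (int mv = 0; mv < moves_per_cycle && ntit > 0; ++mv) {
      int u = (int)std::floor(unif_rand() * ntit);
      if (u == ntit) u = ntit - 1;
      int i = tit_idx0[u];
      bool ionized = (q[i] != 0.0);
      ++attempted;
      if (!explicit_ions) {
        if (ionized) { // deprotonation, xi = +1, insert one implicit cation
          double dU = -tit_valence * site_elec_per_charge(s, nact, i, f, -1);
          double lnacc = -dU + ln10 * (pH - pKa);
          if (lnacc >= 0.0 || unif_rand() < std::exp(lnacc)) {
            q[i] = 0.0; ++cat; ++accepted;
          }
        } else {       // protonation, xi = -1, delete one implicit cation
          if (cat < 1) continue; // no deletable cation: auto-reject
          double dU = tit_valence * site_elec_per_charge(s, nact, i, f, -1);
          double lnacc = -dU - ln10 * (pH - pKa);
          if (lnacc >= 0.0 || unif_rand() < std::exp(lnacc)) {
            q[i] = tit_valence; --cat; ++accepted;
          }
        }
      } else {
        if (ionized) { // deprotonate site + insert a real cation
          if (nact >= ncap) stop("ion capacity exhausted");
          double dU = -tit_valence * site_elec_per_charge(s, nact, i, f, -1);
          int k = nact;
          s.x[k] = L * unif_rand();
          s.y[k] = L * unif_rand();
          s.z[k] = L * unif_rand();
          q[k] = 1.0;
          double qi_old = q[i];
          q[i] = 0.0;
          double Uk = particle_energy(s, nact + 1, k, f);
          double dUtot = dU + Uk;
          double lnacc = -dUtot + ln10 * (pH - pKa);
          bool ok = R_finite(dUtot) &&
                    (lnacc >= 0.0 || unif_rand() < std::exp(lnacc));
          if (ok) {
            vx[k] = norm_rand(); vy[k] = norm_rand(); vz[k] = norm_rand();
            ++nact; ++ncat_expl; ++accepted;
          } else {
            q[i] = qi_old;
            q[k] = 0.0;
          }
        } else {       // protonate site + delete a random cation
          if (ncat_expl < 1) continue; // auto-reject
          int pick = (int)std::floor(unif_rand() * ncat_expl);
          if (pick == ncat_expl) pick = (int)ncat_expl - 1;
          int k = -1, seen = 0;
          for (int j = n_polymer; j < nact; ++j) {
            if (q[j] > 0.0) {
              if (seen == pick) { k = j; break; }
              ++seen;
            }
          }
          double Uk = particle_energy(s, nact, k, f);
          double dU = tit_valence * site_elec_per_charge(s, nact, i, f, k) - Uk;
          double lnacc = -dU - ln10 * (pH - pKa);
          if (lnacc >= 0.0 || unif_rand() < std::exp(lnacc)) {
            q[i] = tit_valence;
            int last = nact - 1;
            if (k != last) {
              s.x[k] = s.x[last]; s.y[k] = s.y[last]; s.z[k] = s.z[last];
              vx[k] = vx[last]; vy[k] = vy[last]; vz[k] = vz[last];
              q[k] = q[last];
            }
            --nact; --ncat_expl; ++accepted;
          }
        }
      }
    }

    // --- rigid-body translation moves (molecule re-insertion) -----------
    // Uniform random re-insertion of a whole oligocation with Metropolis
    // acceptance: a symmetric proposal that leaves the Boltzmann
    // distribution invariant while making the bound/free exchange of the
    // molecules ergodic on desk-scale runs (plain Langevin exchange is
    // diffusion-limited).
    int nmol = mol_start0.size();
    for (int mv = 0; mv < translation_moves_per_cycle && nmol > 0; ++mv) {
      int m = (int)std::floor(unif_rand() * nmol);
      if (m == nmol) m = nmol - 1;
      int b0 = mol_start0[m], nb = mol_len[m];
      // interaction energy of the molecule with everything outside it
      double Uold = 0.0;
      bool overlap = false;
      for (int b = b0; b < b0 + nb; ++b) {
        for (int j = 0; j < nact; ++j) {
          if (j >= b0 && j < b0 + nb) continue;
          double dx, dy, dz;
          double r2 = dist2(s, b, j, &dx, &dy, &dz);
          if (r2 < 1e-14) { overlap = true; break; }
          Uold += pair_energy(r2, s.q[b] * s.q[j], f);
        }
        if (overlap) break;
      }
      if (overlap) continue;
      double cx = 0, cy = 0, cz = 0;
      for (int b = b0; b < b0 + nb; ++b) { cx += s.x[b]; cy += s.y[b]; cz += s.z[b]; }
      cx /= nb; cy /= nb; cz /= nb;
      double tx = L * unif_rand() - cx, ty = L * unif_rand() - cy,
             tz = L * unif_rand() - cz;
      for (int b = b0; b < b0 + nb; ++b) { s.x[b] += tx; s.y[b] += ty; s.z[b] += tz; }
      double Unew = 0.0;
      for (int b = b0; b < b0 + nb; ++b) {
        for (int j = 0; j < nact; ++j) {
          if (j >= b0 && j < b0 + nb) continue;
          double dx, dy, dz;
          double r2 = dist2(s, b, j, &dx, &dy, &dz);
          if (r2 < 1e-14) { Unew = R_PosInf; break; }
          Unew += pair_energy(r2, s.q[b] * s.q[j], f);
        }
        if (!R_finite(Unew)) break;
      }
      double dU = Unew - Uold;
      bool ok = R_finite(dU) && (dU <= 0.0 || unif_rand() < std::exp(-dU));
      if (!ok) { // revert
        for (int b = b0; b < b0 + nb; ++b) {
          s.x[b] -= tx; s.y[b] -= ty; s.z[b] -= tz;
        }
      }
    }

    // --- hard electroneutrality assertion -------------------------------
    double qtot = 0.0;
    for (int j = 0; j < nact; ++j) qtot += q[j];
    if (!explicit_ions) qtot += (double)(cat - an);
    if (std::fabs(qtot) > 1e-9)
      stop("electroneutrality violated after MC sweep (net charge %f)", qtot);

    // --- Langevin dynamics block ----------------------------------------
    if (ld_steps_per_cycle > 0) {
      forces_raw(s, nact, bonds0, f, fx.data(), fy.data(), fz.data());
      ld_steps(s, vx, vy, vz, nact, bonds0, f, dt, gamma, ld_steps_per_cycle,
               fx.data(), fy.data(), fz.data());
      for (int j = 0; j < nact; ++j) {
        if (!R_finite(s.x[j]) || !R_finite(s.y[j]) || !R_finite(s.z[j]))
          stop("Langevin step diverged (non-finite coordinates); "
               "timestep dt = %g is unstable for this system", dt);
      }
    }

    // --- record ----------------------------------------------------------
    if (cyc >= warmup_cycles) {
      int r = cyc - warmup_cycles;
      NumericMatrix fp(nact, 3);
      NumericVector fq(nact);
      for (int j = 0; j < nact; ++j) {
        fp(j, 0) = s.x[j]; fp(j, 1) = s.y[j]; fp(j, 2) = s.z[j];
        fq[j] = q[j];
      }
      frames[r] = List::create(_["pos"] = fp, _["q"] = fq);
      double a = 0.0;
      for (int t = 0; t < ntit; ++t) a += (q[tit_idx0[t]] != 0.0) ? 1.0 : 0.0;
      rec_alpha[r] = ntit > 0 ? a / ntit : NA_REAL;
      rec_epot[r] = total_energy_raw(s, nact, bonds0, f);
      double ke = 0.0;
      for (int j = 0; j < nact; ++j)
        ke += vx[j] * vx[j] + vy[j] * vy[j] + vz[j] * vz[j];
      rec_ekin[r] = 0.5 * ke;
      rec_acc[r] = attempted > 0 ? (double)accepted / attempted : NA_REAL;
      rec_cat[r] = explicit_ions ? (double)ncat_expl : (double)cat;
      rec_an[r] = explicit_ions ? (double)(nact - n_polymer - ncat_expl)
                                : (double)an;
      rec_cycle[r] = cyc + 1;
    }
  }

  return List::create(
      _["frames"] = frames,
      _["cycle"] = rec_cycle,
      _["alpha"] = rec_alpha,
      _["epot"] = rec_epot,
      _["ekin"] = rec_ekin,
      _["acceptance"] = rec_acc,
      _["cations"] = rec_cat,
      _["anions"] = rec_an,
      _["final"] = List::create(
          _["pos"] = pos, _["vel"] = vel, _["q"] = q,
          _["n_active"] = nact,
          _["implicit_cations"] = (double)cat,
          _["implicit_anions"] = (double)an));
}
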