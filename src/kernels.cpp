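#include <Rcpp.h>
using namespace Rcpp;

// Pairwise Coulomb + 12-6 Lennard-Jones with plain cutoff truncation.
// Units: nm, kJ/mol, elementary charge. Lorentz-Berthelot combination is
// applied here from per-atom sigma/epsilon.

static inline void pair_accumulate(double dx, double dy, double dz,
                                   double qi, double qj,
                                   double si, double sj,
                                   double ei, double ej,
                                   double cutoff2, double fcoul,
                                   double dielectric, double clamp,
                                   double &eelec, double &evdw) {
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 > cutoff2) return;
  double r = std::sqrt(r2);
  double rc = r < clamp ? clamp : r;
  eelec += fcoul * qi * qj / (dielectric * rc);
  double sij = 0.5 * (si + sj);
  double eij = std::sqrt(ei * ej);
  if (eij > 0.0 && r > 0.0) {
    double sr2 = (sij * sij) / r2;
    double sr6 = sr2 * sr2 * sr2;
    evdw += 4.0 * eij * sr6 * (sr6 - 1.0);
  }
}

// [[Rcpp::export]]
NumericVector nb_energy_cpp(NumericMatrix lig, NumericVector lq,
                            NumericVector ls, NumericVector le,
                            NumericMatrix rec, NumericVector rq,
                            NumericVector rs, NumericVector re,
                            double cutoff, double fcoul,
                            double dielectric, double clamp) {
  const int L = lig.nrow(), R = rec.nrow();
  const double cutoff2 = cutoff * cutoff;
  double eelec = 0.0, evdw = 0.0;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < R; ++j) {
      pair_accumulate(lig(i, 0) - rec(j, 0), lig(i, 1) - rec(j, 1),
                      lig(i, 2) - rec(j, 2), lq[i], rq[j], ls[i], rs[j],
                      le[i], re[j], cutoff2, fcoul, dielectric, clamp,
                      eelec, evdw);
    }
  }
  return NumericVector::create(_["e_elec"] = eelec, _["e_vdw"] = evdw);
}

// Energies for the ligand rigidly translated by each row of `trans`.
// [[Rcpp::export]]
NumericMatrix nb_energy_batch_cpp(NumericMatrix lig, NumericMatrix trans,
                                  NumericVector lq, NumericVector ls,
                                  NumericVector le, NumericMatrix rec,
                                  NumericVector rq, NumericVector rs,
                                  NumericVector re, double cutoff,
                                  double fcoul, double dielectric,
                                  double clamp) {
  const int L = lig.nrow(), R = rec.nrow(), P = trans.nrow();
  const double cutoff2 = cutoff * cutoff;
  NumericMatrix out(P, 2);
  for (int p = 0; p < P; ++p) {
    double eelec = 0.0, evdw = 0.0;
    const double tx = trans(p, 0), ty = trans(p, 1), tz = trans(p, 2);
    for (int i = 0; i < L; ++i) {
      const double xi = lig(i, 0) + tx, yi = lig(i, 1) + ty,
                   zi = lig(i, 2) + tz;
      for (int j = 0; j < R; ++j) {
        pair_accumulate(xi - rec(j, 0), yi - rec(j, 1), zi - rec(j, 2),
                        lq[i], rq[j], ls[i], rs[j], le[i], re[j], cutoff2,
                        fcoul, dielectric, clamp, eelec, evdw);
      }
    }
    out(p, 0) = eelec;
    out(p, 1) = evdw;
  }
  colnames(out) = CharacterVector::create("e_elec", "e_vdw");
  return out;
}

// Force of atom i due to atom j (accumulated into fx/fy/fz of atom i).
// Returns false when the pair is closer than the clamp distance (overlap
// deeper than the guard): the integrator aborts in that case.
static inline bool pair_force(double dx, double dy, double dz,
                              double qi, double qj,
                              double si, double sj,
                              double ei, double ej,
                              double cutoff2, double fcoul,
                              double dielectric, double clamp,
                              double &fx, double &fy, double &fz) {
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 > cutoff2) return true;
  double r = std::sqrt(r2);
  if (r < clamp) return false;
  // -dE/dr for Coulomb (flat below clamp, so always r here) and LJ
  double dEdr = -fcoul * qi * qj / (dielectric * r2);
  double sij = 0.5 * (si + sj);
  double eij = std::sqrt(ei * ej);
  if (eij > 0.0) {
    double sr2 = (sij * sij) / r2;
    double sr6 = sr2 * sr2 * sr2;
    dEdr += -24.0 * eij / r * sr6 * (2.0 * sr6 - 1.0);
  }
  double fmag = -dEdr / r;  // along +rij for repulsion
  fx += fmag * dx;
  fy += fmag * dy;
  fz += fmag * dz;
  return true;
}

// Overdamped Langevin pulling interval. Receptor fixed; the moving-spring
// force k*(v*t_local - x_proj) acts along `dir` on the pulled atom only;
// every ligand atom feels ligand-receptor nonbonded forces and (optionally)
// intra-ligand nonbonded forces. Profile is sampled every step.
// [[Rcpp::export]]
List run_interval_cpp(NumericMatrix lig, NumericVector lq, NumericVector ls,
                      NumericVector le, NumericMatrix rec, NumericVector rq,
                      NumericVector rs, NumericVector re, NumericVector dir,
                      int pulled, double k, double v, double tau, double dt,
                      double gamma, double kT, double cutoff, double fcoul,
                      double dielectric, double clamp, double t0, double x0,
                      bool include_intra, NumericVector dummy0) {
  const int L = lig.nrow(), R = rec.nrow();
  const int nsteps = (int)std::lround(tau / dt);
  const double cutoff2 = cutoff * cutoff;
  const double noise = kT > 0.0 ? std::sqrt(2.0 * kT * dt / gamma) : 0.0;

  NumericMatrix pos(clone(lig));
  NumericVector times(nsteps), forces(nsteps), disps(nsteps);
  const double p0x = pos(pulled, 0), p0y = pos(pulled, 1),
               p0z = pos(pulled, 2);
  // dummy atom: a 3-D point advancing at v along dir, linked to the pulled
  // atom by a 3-D harmonic spring; its position persists across intervals
  double Dx = dummy0[0], Dy = dummy0[1], Dz = dummy0[2];
  std::vector<double> fx(L), fy(L), fz(L);
  bool aborted = false;
  int abort_step = -1;

  for (int s = 0; s < nsteps && !aborted; ++s) {
    double tl = s * dt;  // time at start of step, local to the interval
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int i = 0; i < L && !aborted; ++i) {
      for (int j = 0; j < R; ++j) {
        if (!pair_force(pos(i, 0) - rec(j, 0), pos(i, 1) - rec(j, 1),
                        pos(i, 2) - rec(j, 2), lq[i], rq[j], ls[i], rs[j],
                        le[i], re[j], cutoff2, fcoul, dielectric, clamp,
                        fx[i], fy[i], fz[i])) {
          aborted = true;
          abort_step = s;
          break;
        }
      }
      if (aborted) break;
      if (include_intra) {
        for (int j = i + 1; j < L; ++j) {
          double gx = 0.0, gy = 0.0, gz = 0.0;
          if (!pair_force(pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1),
                          pos(i, 2) - pos(j, 2), lq[i], lq[j], ls[i], ls[j],
                          le[i], le[j], cutoff2, fcoul, dielectric, clamp,
                          gx, gy, gz)) {
            aborted = true;
            abort_step = s;
            break;
          }
          fx[i] += gx; fy[i] += gy; fz[i] += gz;
          fx[j] -= gx; fy[j] -= gy; fz[j] -= gz;
        }
      }
    }
    if (aborted) break;
    (void)tl;
    fx[pulled] += k * (Dx - pos(pulled, 0));
    fy[pulled] += k * (Dy - pos(pulled, 1));
    fz[pulled] += k * (Dz - pos(pulled, 2));
    for (int i = 0; i < L; ++i) {
      if (!std::isfinite(fx[i]) || !std::isfinite(fy[i]) ||
          !std::isfinite(fz[i])) {
        aborted = true;
        abort_step = s;
        break;
      }
      pos(i, 0) += fx[i] / gamma * dt + (noise > 0.0 ? noise * norm_rand() : 0.0);
      pos(i, 1) += fy[i] / gamma * dt + (noise > 0.0 ? noise * norm_rand() : 0.0);
      pos(i, 2) += fz[i] / gamma * dt + (noise > 0.0 ? noise * norm_rand() : 0.0);
    }
    if (aborted) break;
    Dx += v * dt * dir[0];
    Dy += v * dt * dir[1];
    Dz += v * dt * dir[2];
    double tl1 = (s + 1) * dt;
    double xproj1 = (pos(pulled, 0) - p0x) * dir[0] +
                    (pos(pulled, 1) - p0y) * dir[1] +
                    (pos(pulled, 2) - p0z) * dir[2];
    times[s] = t0 + tl1;
    // recorded force: spring force component along the pulling direction
    forces[s] = k * ((Dx - pos(pulled, 0)) * dir[0] +
                     (Dy - pos(pulled, 1)) * dir[1] +
                     (Dz - pos(pulled, 2)) * dir[2]);
    disps[s] = x0 + xproj1;
  }

  int n = aborted ? abort_step : nsteps;
  return List::create(
      _["positions"] = pos,
      _["times"] = times[Range(0, std::max(n - 1, 0))],
      _["forces"] = forces[Range(0, std::max(n - 1, 0))],
      _["displacements"] = disps[Range(0, std::max(n - 1, 0))],
      _["dummy"] = NumericVector::create(Dx, Dy, Dz),
      _["aborted"] = aborted, _["abort_step"] = abort_step + 1,
      _["n_recorded"] = n);
}
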