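// Bead-model force field and BAOAB Langevin integrator.
//
// Units: length Angstrom, energy kcal/mol, mass amu, time ps.
// F_ACC converts (kcal/mol/A)/amu to A/ps^2; KB is Boltzmann's constant
// in kcal/mol/K.

#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

static const double F_ACC = 418.4;
static const double KB = 0.0019872041;

struct ForceField {
  IntegerMatrix bonds;      // m x 2, 1-based bead indices
  NumericVector bond_r0, bond_k;
  IntegerMatrix contacts;   // m x 2
  NumericVector con_r0a, con_r0b, con_k;   // r0b used only in dual mode
  bool dual;
  double beta_mix;
  double sigma, eps;
  NumericVector pos_k;      // per-bead tether constants (length 0 = none)
  NumericMatrix pos_ref;
};

static ForceField parse_ff(const List& ff) {
  ForceField f;
  f.bonds = as<IntegerMatrix>(ff["bonds"]);
  f.bond_r0 = as<NumericVector>(ff["bond_r0"]);
  f.bond_k = as<NumericVector>(ff["bond_k"]);
  f.contacts = as<IntegerMatrix>(ff["contacts"]);
  f.con_r0a = as<NumericVector>(ff["contact_r0"]);
  f.con_k = as<NumericVector>(ff["contact_k"]);
  f.dual = as<bool>(ff["dual"]);
  if (f.dual) {
    f.con_r0b = as<NumericVector>(ff["contact_r0_b"]);
    f.beta_mix = as<double>(ff["beta_mix"]);
  } else {
    f.beta_mix = 0.0;
  }
  f.sigma = as<double>(ff["sigma"]);
  f.eps = as<double>(ff["eps"]);
  if (ff.containsElementNamed("pos_k") && !Rf_isNull(ff["pos_k"])) {
    f.pos_k = as<NumericVector>(ff["pos_k"]);
    f.pos_ref = as<NumericMatrix>(ff["pos_ref"]);
  }
  return f;
}

// pairwise harmonic sum over one contact-set r0; forces accumulated scaled by w
static double contact_energy(const NumericMatrix& x, const IntegerMatrix& c,
                             const NumericVector& r0, const NumericVector& k,
                             NumericMatrix* F, double w) {
  double E = 0.0;
  for (int p = 0; p < c.nrow(); ++p) {
    int i = c(p, 0) - 1, j = c(p, 1) - 1;
    double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1), dz = x(i, 2) - x(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - r0[p];
    E += k[p] * dr * dr;
    if (F && r > 1e-12) {
      double fmag = -2.0 * k[p] * dr / r * w;
      (*F)(i, 0) += fmag * dx; (*F)(i, 1) += fmag * dy; (*F)(i, 2) += fmag * dz;
      (*F)(j, 0) -= fmag * dx; (*F)(j, 1) -= fmag * dy; (*F)(j, 2) -= fmag * dz;
    }
  }
  return E;
}

// total potential; fills F (overwritten) when non-null
static double ff_energy(const NumericMatrix& x, const ForceField& f,
                        NumericMatrix* F) {
  int n = x.nrow();
  if (F) std::fill(F->begin(), F->end(), 0.0);
  double E = contact_energy(x, f.bonds, f.bond_r0, f.bond_k, F, 1.0);

  if (!f.dual) {
    E += contact_energy(x, f.contacts, f.con_r0a, f.con_k, F, 1.0);
  } else {
    // V_mix = -(1/beta) log(exp(-beta V1) + exp(-beta V2)), force-mixed by
    // the Boltzmann weights of the two basins (log-sum-exp stabilized)
    NumericMatrix F1(n, 3), F2(n, 3);
    double V1 = contact_energy(x, f.contacts, f.con_r0a, f.con_k,
                               F ? &F1 : nullptr, 1.0);
    double V2 = contact_energy(x, f.contacts, f.con_r0b, f.con_k,
                               F ? &F2 : nullptr, 1.0);
    double b = f.beta_mix;
    double vmin = std::min(V1, V2);
    double e1 = std::exp(-b * (V1 - vmin)), e2 = std::exp(-b * (V2 - vmin));
    double Vmix = vmin - std::log(e1 + e2) / b;
    double w1 = e1 / (e1 + e2), w2 = 1.0 - w1;
    E += Vmix;
    if (F)
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a)
          (*F)(i, a) += w1 * F1(i, a) + w2 * F2(i, a);
  }

  // soft excluded volume: WCA-like, zero beyond sigma
  double s2 = f.sigma * f.sigma;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1), dz = x(i, 2) - x(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= s2 || r2 < 1e-12) continue;
      double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
      E += f.eps * (sr12 - 2.0 * sr6 + 1.0);
      if (F) {
        double fr = f.eps * 12.0 * (sr12 - sr6) / r2;  // -dV/dr / r
        (*F)(i, 0) += fr * dx; (*F)(i, 1) += fr * dy; (*F)(i, 2) += fr * dz;
        (*F)(j, 0) -= fr * dx; (*F)(j, 1) -= fr * dy; (*F)(j, 2) -= fr * dz;
      }
    }

  if (f.pos_k.size() > 0) {
    for (int i = 0; i < n; ++i) {
      double k = f.pos_k[i];
      if (k <= 0) continue;
      for (int a = 0; a < 3; ++a) {
        double d = x(i, a) - f.pos_ref(i, a);
        E += k * d * d;
        if (F) (*F)(i, a) += -2.0 * k * d;
      }
    }
  }
  return E;
}

// harmonic distance-restraint coupling: E = k * sum_p (d_p - target_p)^2
static double coupling(const NumericMatrix& x, const IntegerMatrix& pairs,
                       const NumericVector& target, double k,
                       NumericMatrix* F) {
  if (k == 0.0 || pairs.nrow() == 0) return 0.0;
  double E = 0.0;
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1), dz = x(i, 2) - x(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - target[p];
    E += k * dr * dr;
    if (F && r > 1e-12) {
      double fmag = -2.0 * k * dr / r;
      (*F)(i, 0) += fmag * dx; (*F)(i, 1) += fmag * dy; (*F)(i, 2) += fmag * dz;
      (*F)(j, 0) -= fmag * dx; (*F)(j, 1) -= fmag * dy; (*F)(j, 2) -= fmag * dz;
    }
  }
  return E;
}

// [[Rcpp::export]]
List cpp_coupling_energy(NumericMatrix coords, IntegerMatrix pairs,
                         NumericVector target, double k) {
  NumericMatrix F(coords.nrow(), 3);
  double E = coupling(coords, pairs, target, k, &F);
  return List::create(_["energy"] = E, _["forces"] = F);
}

// [[Rcpp::export]]
List cpp_ff_energy(NumericMatrix coords, List ff) {
  ForceField f = parse_ff(ff);
  NumericMatrix F(coords.nrow(), 3);
  double E = ff_energy(coords, f, &F);
  return List::create(_["energy"] = E, _["forces"] = F);
}

// BAOAB Langevin trajectory. Restraint target held fixed for the run
// (one exchange window). gamma = 0 with temperature > 0 still applies no
// thermostat noise, reducing to velocity Verlet.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords, NumericMatrix vels,
                      NumericVector mass, List ff,
                      IntegerMatrix pairs, NumericVector target, double k_coup,
                      int n_steps, double dt, double gamma, double temperature,
                      double seed, int save_every) {
  ForceField f = parse_ff(ff);
  int n = coords.nrow();
  NumericMatrix x(clone(coords)), v(clone(vels));
  NumericMatrix F(n, 3);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  double c1 = std::exp(-gamma * dt);
  double c2 = (gamma > 0.0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  std::vector<double> sig(n);
  for (int i = 0; i < n; ++i)
    sig[i] = std::sqrt(KB * temperature * F_ACC / mass[i]);

  int n_save = (save_every > 0) ? n_steps / save_every : 0;
  NumericVector frames(n_save > 0 ? (R_xlen_t)n_save * n * 3 : 0);
  NumericVector epot(n_save > 0 ? n_save : 0);
  int isave = 0;

  double E = ff_energy(x, f, &F);
  E += coupling(x, pairs, target, k_coup, &F);

  for (int s = 0; s < n_steps; ++s) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double fac = 0.5 * dt * F_ACC / mass[i];
      for (int a = 0; a < 3; ++a) v(i, a) += fac * F(i, a);
    }
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a) x(i, a) += 0.5 * dt * v(i, a);
    // O: friction + noise
    if (gamma > 0.0 && temperature >= 0.0)
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a)
          v(i, a) = c1 * v(i, a) + c2 * sig[i] * gauss(rng);
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a) x(i, a) += 0.5 * dt * v(i, a);
    // force at new positions, B: half kick
    E = ff_energy(x, f, &F);
    E += coupling(x, pairs, target, k_coup, &F);
    for (int i = 0; i < n; ++i) {
      double fac = 0.5 * dt * F_ACC / mass[i];
      for (int a = 0; a < 3; ++a) v(i, a) += fac * F(i, a);
    }
    if (save_every > 0 && (s + 1) % save_every == 0) {
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a)
          frames[(R_xlen_t)isave + (R_xlen_t)n_save * (i + (R_xlen_t)n * a)] = x(i, a);
      epot[isave] = E;
      ++isave;
    }
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a)
        if (!std::isfinite(x(i, a)) || std::fabs(x(i, a)) > 1e6)
          stop("coordinate blow-up at step %d (bead %d); reduce dt or forces",
               s + 1, i + 1);
  }

  List out = List::create(_["coords"] = x, _["vels"] = v,
                          _["energy"] = E, _["n_saved"] = isave);
  if (n_save > 0) {
    frames.attr("dim") = IntegerVector::create(n_save, n, 3);
    out["frames"] = frames;
    out["epot"] = epot;
  }
  return out;
}
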