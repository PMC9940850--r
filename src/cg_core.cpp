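// Compiled kernels for the coarse-grained force field, the Langevin
// integrator and interchain contact counting.  Cubic periodic box with
// minimum-image convention throughout; O(N^2) pair loops with early cutoff
// rejection, which is ample at the desk scales this package targets.
#include <Rcpp.h>
#include <unordered_set>
#include <map>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

// key for an unordered pair (i < j)
static inline long long pair_key(int i, int j, int n) {
  return (long long)i * n + j;
}

struct FFParams {
  double bond_r0, bond_k, eps_stst, lambda_d, dh_pref, lj_cut, dh_cut;
};

// pair epsilon from sticker classes: St-St = eps, St-Sp = eps/1.5, Sp-Sp = eps/3
static inline double pair_eps(int si, int sj, double eps_stst) {
  int ns = si + sj;
  if (ns == 2) return eps_stst;
  if (ns == 1) return eps_stst / 1.5;
  return eps_stst / 3.0;
}

static void eval_energy_forces(const NumericMatrix &coords, double box,
                               const NumericVector &sigma,
                               const IntegerVector &sticker,
                               const NumericVector &charge,
                               const IntegerMatrix &bonds,
                               const FFParams &p, bool want_forces,
                               double &e_bond, double &e_lj, double &e_dh,
                               NumericMatrix &forces) {
  const int n = coords.nrow();
  e_bond = e_lj = e_dh = 0.0;
  if (want_forces) std::fill(forces.begin(), forces.end(), 0.0);
  std::unordered_set<long long> excl;
  const int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    if (i > j) std::swap(i, j);
    excl.insert(pair_key(i, j, n));
  }
  // bonded terms
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = min_image(coords(i, 0) - coords(j, 0), box);
    double dy = min_image(coords(i, 1) - coords(j, 1), box);
    double dz = min_image(coords(i, 2) - coords(j, 2), box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - p.bond_r0;
    e_bond += 0.5 * p.bond_k * dr * dr;
    if (want_forces && r > 0) {
      double fmag = -p.bond_k * dr / r; // dU/dr = k*dr; F = -dU/dr * rhat
      forces(i, 0) += fmag * dx; forces(i, 1) += fmag * dy; forces(i, 2) += fmag * dz;
      forces(j, 0) -= fmag * dx; forces(j, 1) -= fmag * dy; forces(j, 2) -= fmag * dz;
    }
  }
  const double cut2max = std::pow(std::max(p.lj_cut, p.dh_cut), 2);
  const double lj_cut2 = p.lj_cut * p.lj_cut, dh_cut2 = p.dh_cut * p.dh_cut;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (excl.count(pair_key(i, j, n))) continue;
      double dx = min_image(coords(i, 0) - coords(j, 0), box);
      double dy = min_image(coords(i, 1) - coords(j, 1), box);
      double dz = min_image(coords(i, 2) - coords(j, 2), box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut2max) continue;
      double r = std::sqrt(r2);
      double dudr = 0.0;
      if (r2 <= lj_cut2) {
        double sij = 0.5 * (sigma[i] + sigma[j]);
        double eij = pair_eps(sticker[i], sticker[j], p.eps_stst);
        double sr2 = sij * sij / r2;
        double sr6 = sr2 * sr2 * sr2;
        double sr12 = sr6 * sr6;
        e_lj += 4.0 * eij * (sr12 - sr6);
        dudr += 4.0 * eij * (-12.0 * sr12 + 6.0 * sr6) / r;
      }
      if (r2 <= dh_cut2 && charge[i] != 0.0 && charge[j] != 0.0) {
        double pref = p.dh_pref * charge[i] * charge[j];
        double ex = std::exp(-r / p.lambda_d);
        double u = pref * ex / r;
        e_dh += u;
        dudr += -u * (1.0 / r + 1.0 / p.lambda_d);
      }
      if (want_forces && dudr != 0.0) {
        double fmag = -dudr / r;
        forces(i, 0) += fmag * dx; forces(i, 1) += fmag * dy; forces(i, 2) += fmag * dz;
        forces(j, 0) -= fmag * dx; forces(j, 1) -= fmag * dy; forces(j, 2) -= fmag * dz;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, double box, NumericVector sigma,
                       IntegerVector sticker, NumericVector charge,
                       IntegerMatrix bonds, double bond_r0, double bond_k,
                       double eps_stst, double lambda_d, double dh_pref,
                       double lj_cut, double dh_cut, bool want_forces) {
  FFParams p{bond_r0, bond_k, eps_stst, lambda_d, dh_pref, lj_cut, dh_cut};
  NumericMatrix forces(want_forces ? coords.nrow() : 1, 3);
  double eb, el, ed;
  eval_energy_forces(coords, box, sigma, sticker, charge, bonds, p,
                     want_forces, eb, el, ed, forces);
  return List::create(_["energy"] = eb + el + ed, _["e_bond"] = eb,
                      _["e_lj"] = el, _["e_dh"] = ed,
                      _["forces"] = want_forces ? forces : NumericMatrix(0, 3));
}

// BAOAB Langevin integrator.  Uses R's RNG (norm_rand) so that set.seed()
// on the R side makes trajectories bitwise reproducible.  Coordinates are
// propagated unwrapped; the minimum-image convention handles periodicity
// in the force evaluation, and analysis code wraps as needed.
// [[Rcpp::export]]
List cpp_langevin(NumericMatrix coords0, double box, NumericVector sigma,
                  IntegerVector sticker, NumericVector charge,
                  IntegerMatrix bonds, double bond_r0, double bond_k,
                  double eps_stst, double lambda_d, double dh_pref,
                  double lj_cut, double dh_cut, double mass, double dt,
                  double friction, double kT, int n_steps, int save_every) {
  FFParams p{bond_r0, bond_k, eps_stst, lambda_d, dh_pref, lj_cut, dh_cut};
  const int n = coords0.nrow();
  NumericMatrix x(clone(coords0));
  NumericMatrix v(n, 3), f(n, 3);
  const double vscale = std::sqrt(kT / mass);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) v(i, d) = vscale * norm_rand();
  double eb, el, ed;
  eval_energy_forces(x, box, sigma, sticker, charge, bonds, p, true, eb, el, ed, f);
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1) * vscale;
  const double hdt = 0.5 * dt;
  int n_frames = n_steps / save_every + 1;
  List frames(n_frames);
  NumericVector e_pot(n_frames);
  frames[0] = clone(x);
  e_pot[0] = eb + el + ed;
  int fidx = 1, bad_step = -1;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        v(i, d) += hdt * f(i, d) / mass;
        x(i, d) += hdt * v(i, d);
        v(i, d) = c1 * v(i, d) + c2 * norm_rand();
        x(i, d) += hdt * v(i, d);
      }
    eval_energy_forces(x, box, sigma, sticker, charge, bonds, p, true, eb, el, ed, f);
    bool ok = true;
    for (int i = 0; i < n && ok; ++i)
      for (int d = 0; d < 3; ++d)
        if (!std::isfinite(f(i, d))) { ok = false; break; }
    if (!ok) { bad_step = s; break; }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v(i, d) += hdt * f(i, d) / mass;
    if (s % save_every == 0) {
      frames[fidx] = clone(x);
      e_pot[fidx] = eb + el + ed;
      ++fidx;
    }
  }
  return List::create(_["frames"] = frames, _["e_pot"] = e_pot,
                      _["n_saved"] = fidx, _["bad_step"] = bad_step);
}

// Count interchain bead-bead contacts (pairs within cutoff, minimum image).
// Returns a 3-column matrix (chain_i, chain_j, n_contacts), 1-based chains.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_counts(NumericMatrix coords, double box,
                                 IntegerVector chain, double cutoff) {
  const int n = coords.nrow();
  const double cut2 = cutoff * cutoff;
  std::map<std::pair<int, int>, int> counts;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (chain[i] == chain[j]) continue;
      double dx = min_image(coords(i, 0) - coords(j, 0), box);
      if (std::fabs(dx) > cutoff) continue;
      double dy = min_image(coords(i, 1) - coords(j, 1), box);
      if (std::fabs(dy) > cutoff) continue;
      double dz = min_image(coords(i, 2) - coords(j, 2), box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= cut2) {
        int ci = chain[i], cj = chain[j];
        if (ci > cj) std::swap(ci, cj);
        counts[{ci, cj}]++;
      }
    }
  }
  IntegerMatrix out(counts.size(), 3);
  int k = 0;
  for (auto &kv : counts) {
    out(k, 0) = kv.first.first;
    out(k, 1) = kv.first.second;
    out(k, 2) = kv.second;
    ++k;
  }
  return out;
}
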