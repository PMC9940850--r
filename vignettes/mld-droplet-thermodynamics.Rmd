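---
title: "Canonical droplet thermodynamics: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical droplet thermodynamics: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mldroplet)
```

This vignette is the package's account of the science it implements: the
canonical (NVT) droplet free energy and its assumptions, the estimators
built on it, the defaults and why they were chosen, what the synthetic
generators do and do not emulate, and the numerical decisions a maintainer
would want written down.

## The canonical droplet model

Classical nucleation theory (CNT) writes the reversible work of forming an
`n`-chain droplet from a supersaturated solution at fixed density
$\rho_d^\circ$ as a bulk gain against a surface penalty,

$$\beta F_\infty(n) = -n \ln S + \beta\sigma A(n), \qquad
S = \rho_d^\circ/\rho_d^*,$$

with $A(n) = (36\pi)^{1/3}(n/\rho_c)^{2/3}$ under the spherical-droplet
assumption. In a closed simulation box this is wrong in an essential way:
the $n$ chains in the droplet are removed from a finite reservoir, so the
dilute phase is depleted to

$$\rho_d^{\,n} = \frac{N-n}{V - n/\rho_c},$$

which both subtracts chains and credits the droplet's excluded volume. The
finite-size free energy used throughout the package is the unique profile
that (i) vanishes at $n = 0$ (the homogeneous reference state) and (ii) has
stationary points satisfying the Gibbs–Thomson/Kelvin relation exactly:

$$\beta F(n) = \beta\sigma A(n)
  - \int_0^n \ln\!\frac{\rho_d^{\,n'}}{\rho_d^*}\, dn'.$$

Uniqueness is immediate: (ii) forces
$dF/dn = \beta\sigma A'(n) - \ln(\rho_d^{\,n}/\rho_d^*)$, and (i) fixes the
integration constant. The integral has the closed form

$$\beta F(n) = \beta\sigma A(n) - n\ln S
  + (N-n)\,\mathrm{log1p}(-n/N)
  + (n - V\rho_c)\,\mathrm{log1p}\!\big(-n/(V\rho_c)\big),$$

implemented with `log1p` so that boxes of $10^6$–$10^7$ chains evaluate
without cancellation (the two logarithmic terms individually cancel the
$-n$ pieces to first order). The test suite verifies the closed form
against numerical quadrature and the analytic derivative against finite
differences.

Assumptions inherited from CNT and kept here: the droplet is spherical and
incompressible at the bulk condensed density $\rho_c$; the surface tension
is the planar value, with no curvature (Tolman) correction; the dilute
phase is ideal; exactly one droplet forms. Deviations from sphericity in
real trajectories are quantified separately (`asphericity()`), not fed
back into the free energy.

Two consequences organize the whole analysis:

* **Stationarity = Kelvin relation.** The local minimum of $F$ (the
  self-limiting steady-state droplet, `n_ss`) satisfies
  $\rho_d^{\,n_{ss}} = \rho_d^* \exp\{2\beta\sigma/(\rho_c r_{ss})\}$.
  Each finite box therefore reports one point on a *line* in
  $(2/(\rho_c kT\, r_{ss}),\ \ln\rho_d^{\,n_{ss}})$ space, with slope
  $\sigma$ and intercept $\ln\rho_d^*$. That is the global fit
  (`fit_parameters()`).
* **Macroscopic limit.** At fixed $\rho_d^\circ$ with $N \to \infty$,
  $F \to F_\infty$; the residual finite-size deviation is exactly
  $(1-\rho_d^\circ/\rho_c)\,n^2/2N + O(n^3/N^2)$, which the property tests
  assert (about $1.2\times10^{-3}\,kT$ at $n = 50$, $N = 10^6$, an order
  of magnitude smaller at $N = 10^7$). Barriers and critical sizes in the
  macroscopic limit have the closed forms
  $\beta\Delta F^* = 16\pi(\beta\sigma)^3/(3\rho_c^2\ln^2 S)$ and
  $n^* = 32\pi(\beta\sigma)^3/(3\rho_c^2\ln^3 S)$, cross-checked against
  numerical optimization to $10^{-6}$ relative.

## Units and parameters

All lengths are nm, energies kJ/mol (so $kT \approx 2.494$ kJ/mol at
300 K), densities both mg/mL (user-facing) and chains/nm³ (internal),
linked by the chain molar mass via
$\rho[\mathrm{mg/mL}] = \rho[\mathrm{nm^{-3}}] \cdot M \cdot 1.66054$.
Surface tensions are mN/m user-facing and $kT/\mathrm{nm}^2$ internally
(1 mN/m = 0.24143 $kT/\mathrm{nm}^2$ at 300 K). These conversions are
centralized in `mgml_to_nm3()` / `sigma_to_kT_nm2()` and unit round trips
are tested. `thermo_params()` carries $\sigma$, $\rho_d^*$, $\rho_c$, the
temperature and chain mass; $\rho_c$ is treated as a *measured input* (from
radial density profiles), never a fit parameter — jointly fitting it is
deliberately out of scope because the profile plateau determines it far
more directly than the Kelvin line does.

Chain masses for the packaged tables are derived from the tables' paired
density columns (mg/mL over nm⁻³), giving ≈25.4 kDa and ≈17.2 kDa for the
two packaged proteins; `chain_mass_from_table()` warns when rows imply
masses differing by more than 1%.

## The global fit and its uncertainty

The default objective is ordinary least squares in log-density space,
where the Kelvin relation is linear in the unknowns ($\ln\rho_d^*$,
$\beta\sigma$): scale-free, convex, and with no starting-value issues. A
Levenberg–Marquardt fit in density space (`method = "nonlinear"`) is
provided as a robustness check; on the packaged tables the two agree to
better than 2%. Rows are equally weighted by default — the observation
errors are small and similar across rows, and no weighting scheme is
implied by the data format; inverse-variance weights from the block errors
are available (`weight_by_error`). Only rows flagged `stable` enter:
fluctuating clusters and non-phase-separated boxes do not measure a
steady-state droplet.

Uncertainty comes from a case-resampling bootstrap over rows (default
10 000 replicates, seeded; replicates with fewer than three distinct rows
are redrawn since slope and intercept are then unidentifiable). A caution
that the package makes explicit rather than hiding: the 8–9 condition
design constrains $\sigma$ only through a narrow lever arm in
$1/r_{ss}$, so per-row noise is strongly amplified — with the packaged
NDDX4-like design the 95% band on $\sigma$ spans roughly ±60% of the
estimate. Parameter-recovery tests are therefore calibrated to what the
design supports: at 1% multiplicative noise on $n_{ss}$ the fit recovers
$\sigma$ within 10% in ≳90% of realizations; at 3% noise the median
$\sigma$ error is ~14% and individual realizations scatter accordingly.

`predict_nss()` inverts the fit: bracketed root-finding on
$dF/dn = 0$, selecting the larger root (the minimum). Refitting each
observed condition with the fitted parameters reproduces the observed
sizes to a few chains (the parity check in `print.kelvin_fit()`).

## Droplet detection and profiles

Droplets are identified with a two-stage geometric criterion. Stage 1:
two chains are linked if at least `min_contacts` bead pairs lie within
`contact_cutoff` (default 1 contact within 1.0 nm); single-linkage
components are candidate clusters, singletons are dilute. Stage 2: chains
whose center of mass lies farther than `com_cutoff` from the cluster COM
are demoted to dilute; the default cutoff adapts to twice the cluster's
radius of gyration, which for a uniform sphere (Rg² = 3R²/5) sits at
1.55 R — inside members always pass, stray linked chains do not. All COMs
use circular means per axis, so droplets straddling periodic boundaries
are handled without unwrapping. The exact cutoffs are configurable; the
defaults are stated in the output metadata rather than baked into results.

Steady-state sizes average the largest cluster over the post-equilibration
half of a trajectory with a 5-block standard error. Outcome flags mirror
the bookkeeping conventions of nucleation studies: `none` (no
droplet-sized cluster in ≥90% of frames), `fluctuating` (relative block
error above 25%, or several droplet-sized clusters coexisting in ≥25% of
frames), else `stable`; all thresholds are arguments.

Radial profiles histogram bead mass in 0.5 nm spherical shells about the
droplet COM and average over frames. The condensed-phase density estimate
averages the volume-weighted density over shells within half the
half-density radius; the profile is smoothed over three bins only for
*locating* that radius, because the innermost shells hold few beads and
are the noisiest. The estimator's sampling error on the packaged-scale
fixtures (2 000 beads, 60 frames) is a few percent — "binning error" in
the tests means 7%.

## Exchange kinetics

Single-chain exchange is modeled as a two-state (condensed/dilute) Markov
chain. A chain is condensed iff it belongs to the largest cluster — the
same criterion as detection, so thermodynamic and kinetic analyses cannot
disagree about state definitions. Transition counts use a sliding window
at the chosen lag (default 1 saved frame; an implied-rate flatness check
across lags is the Markovianity diagnostic), pooled over chains, and
optionally stratified by droplet-size quintile. The escape rate is the
reciprocal mean first passage time of the two-state chain,
$k = p_\mathrm{exit}/(\mathrm{lag}\cdot\Delta t)$, with Jeffreys-prior
beta intervals on $p_\mathrm{exit}$; bins with no observed exits report an
upper bound instead of a fake zero. `fit_exponential_decay()` regresses
$\ln k_{cd}$ on droplet size (escape slows roughly exponentially with
size), and `rate_ratio_balance()` checks detailed-balance consistency:
$k_{cd}/k_{dc}$ against $N_\mathrm{dilute}/N_\mathrm{condensed}$, slope 1,
intercept 0 on telegraph fixtures.

## The coarse-grained model and toy simulator

The force field is one bead per residue: harmonic bonds (r₀ = 0.38 nm,
k = 10³ kJ mol⁻¹ nm⁻²), Debye–Hückel electrostatics (screening length
1 nm ≈ 100 mM ionic strength, prefactor = Coulomb constant over ε_r = 80,
charges D/E = −1, K/R = +1, H = 0, all per-residue configurable), and a
12-6 Lennard-Jones contact term. Arg, Phe, Tyr, Trp and Gln are stickers;
the pair well depth follows the class mixing rule
ε(St–St) : ε(St–Sp) : ε(Sp–Sp) = 1 : 1/1.5 : 1/3, held exactly whatever
the absolute scale `eps_stst` — which is the model's single free energy
parameter and is *not* tuned here (tuning against experimental densities
is a non-goal). Per-residue bead sizes default to a standard
one-bead-per-residue van der Waals convention and are an explicit
stand-in, overridable from a delimited file. σ combination is the
arithmetic (Lorentz) mean; only directly bonded 1–2 pairs are excluded
from nonbonded sums; cutoffs default to 2.0 nm (LJ) and 3.5 nm (DH).
These last four choices are conventions, not measurements — nothing in
the analysis stack depends on them.

The integrator is BAOAB Langevin with uniform bead mass (mean residue
mass; chemically faithful inertia is irrelevant at this scale). The
default time step, 10 fs, is set by the stiffest term: the bond gives
ω = √(k/m) ≈ 3 ps⁻¹, a ~2 ps period, resolved ~200-fold. Coordinates are
propagated unwrapped (minimum image handles periodicity in the forces),
which makes diffusion observables trivial. Pair interactions use a
compiled O(N²) minimum-image loop with early cutoff rejection — at the
package's desk scales (≤ a few thousand beads) this is faster than
maintaining a cell list and has no size regime here where that would
flip. Random initial placements can overlap beads; `minimize_energy()`
(capped steepest descent) removes overlaps before dynamics. Correctness
is established by force/finite-difference agreement (10⁻⁵ relative),
harmonic-dimer equipartition (var r = kT/k), free-bead diffusion
(MSD slope = 6kT/mγ), and a condensation smoke test: twenty sticker-rich
chains at eps_stst = 5 kJ/mol (2 kT) grow and keep a cluster that the
eps → 0 control never forms.

## Synthetic fixtures: what they do and do not show

Every generator plants its ground truth and carries it with the data.

* `make_droplet_configuration()` places random-walk coils with COMs
  uniform in a central sphere at the target density, plus vapor chains
  outside an exclusion buffer. It emulates *geometry and density*, not
  liquid structure: there is no interfacial width, no surface
  fluctuation, no pair correlation. Uniform random placement can leave a
  core chain contact-isolated, in which case "membership" is ill-posed —
  `ensure_contact_cutoff` redraws (deterministically) until the planted
  droplet is one contact component, which is the regime real condensates
  occupy. Exact-recovery tests use a clearly percolated core
  (700 mg/mL with 10-bead chains); density-recovery tests use the study
  proteins' densities.
* `make_observation_table()` inverts `predict_nss()` over the packaged
  study design — the printed (L, N) pairs, which differ from
  round(ρ·V) by 1–2 chains — with truncated (±3 sd) multiplicative
  Gaussian noise, matching the few-percent relative block errors of real
  steady-state measurements.
* `make_telegraph_states()` draws independent two-state chains with
  per-frame switching probabilities 1 − exp(−k Δt), started from the
  stationary occupancy.

Passing tests on these fixtures shows the estimators are correct *given
the model assumptions*; it does not validate the assumptions against real
trajectories (interfacial structure, correlated exchange, droplet
translation/coalescence are all absent from the fixtures).

## Numerical choices

* Droplet size `n` is continuous everywhere; reported stationary sizes
  are real-valued.
* Profile grids: 400 points, linear below n = 1 and log-spaced above, up
  to just below min(N, Vρ_c) (the depletion singularity) for finite
  systems, or ten times the CNT critical size (capped at 10⁶, reported
  as divergence beyond) for macroscopic ones. Stationary points never
  depend on the grid: they come from the analytic derivative, bracketed
  by a 1-D minimization of dF/dn and refined with `uniroot` at 10⁻¹²
  tolerance. Profiles are classified `monotonic`, `flex` (|min dF/dn|
  below 10⁻⁸ — the stability-diagram boundary case) or `two_stationary`.
* The stability diagram classifies each (ρ_d°, L) by the sign of
  min_n dF/dn; the boundary is a bisection on L at fixed density. Below
  ρ_d* everything is `unstable` without touching the profile.
* Crossover densities are roots in ln ρ of the difference of closed-form
  CNT expressions, bracket-adjusted near the larger binodal where one
  barrier is still infinite; identical parameter sets are reported as
  degenerate rather than root-found.
* Bootstrap replicates use `lm.fit` on the 2-column design directly
  (~10⁴ replicates in well under a second); all stochastic helpers save
  and restore the caller's RNG state.
* Finite differences in the force tests use relaxed configurations:
  against bead overlaps the r⁻¹² core makes total energies so large that
  centered differences lose the 10⁻⁵ agreement to floating-point
  cancellation, which would test arithmetic, not forces.

## Problem sizes in the test suite

The suite is sized for a single CPU: detector fixtures of 2 000–2 200
beads over 60 frames; Langevin runs of 2×10⁵ steps for a dimer and
6×10⁴ steps for 160 beads; 10⁴-frame telegraph trajectories of 50 chains;
50-seed Monte-Carlo for fit recovery; 10⁴ bootstrap replicates. The whole
suite runs in about a minute.

## Known limitations

* One droplet, spherical, incompressible; no curvature-dependent surface
  tension; no multi-droplet partition function. Near the flex boundary,
  where fluctuations dominate, the mean-field profile is least reliable.
* ρ_c enters both the depletion term and the droplet radius; it is held
  fixed at the profile-derived value, and errors in it propagate to σ
  roughly linearly.
* The Kelvin fit's precision is design-limited (see above); adding
  conditions at more box sizes, not more frames, is what narrows σ.
* The toy simulator is for exercising the analysis stack; it makes no
  claim to reproduce real condensate kinetics or microsecond-scale
  phase behavior.
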