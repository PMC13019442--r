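---
title: "Direct binding free energies from end-state ensembles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct binding free energies from end-state ensembles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbfe)
```

## The estimation problem

We want the standard-state Gibbs free energy of binding for
P + L &rarr; PL from three plain molecular-dynamics ensembles in implicit
solvent: a receptor-only trajectory (samples of `U_P`), a ligand-only
trajectory (`U_L`), and a complex trajectory (`U_PL`). A naive two-state
estimator between the decoupled potential `U_0 = U_P + U_L` and the
coupled potential `U_1 = U_PL` fails because the two ensembles share
almost no phase space: nearly every decoupled configuration, with the
ligand placed anywhere, clashes sterically with the receptor. Alchemical
methods solve this with many intermediate lambda states; this package
instead follows the direct end-state route:

1. **Restrain** the ligand's rigid-body pose `zeta = (t, q)` (translation
   plus rotation quaternion, measured against a reference complex frame
   after pocket alignment) with an analytically integrable potential
   `U_zeta`. The free energy of imposing the restraint on a
   noninteracting ligand at standard concentration, `dG(0 -> r)`, is a
   closed-form/quadrature expression.
2. **Compose and filter.** Because `U_r = U_P + U_L + U_zeta` has no
   cross terms, its Boltzmann ensemble is a product measure: any receptor
   frame, any ligand conformation, and any restraint draw combine into a
   valid sample. Out of `N_P x N_L x N_zeta` combinatorial samples, a
   spatial-index filter keeps the clash-free subset; the conditioning
   free energy is exactly `dG(r -> rc) = -kB T log(alpha)` with `alpha`
   the surviving fraction.
3. **One reweighting step.** The clash-free restrained ensemble overlaps
   the physical complex ensemble well, so a single two-state MBAR
   (equivalently BAR) computation yields `dG(rc -> 1)`.

The total is `dG = dG(0 -> r) + dG(r -> rc) + dG(rc -> 1)`.

## Cycle bookkeeping: where the restraint lives

The three legs telescope exactly only if each intermediate partition
function appears once in a numerator and once in a denominator. We
therefore define the MBAR leg between the *conditional restrained
decoupled* state `U_rc` (restraint included, infinite outside the
clash-free region) and the *physical coupled* state `U_1 = U_PL` with
**no** restraint:

```
dG(0->r)  = -kT log(Z_r / Z_0)
dG(r->rc) = -kT log(Z_rc / Z_r)
dG(rc->1) = -kT log(Z_1 / Z_rc)
sum       = -kT log(Z_1 / Z_0)       (the binding free energy)
```

The alternative convention -- carrying `U_zeta` into the coupled end
state as well -- leaves a residual `-kT log < exp(-U_zeta/kT) >_1` that
does not cancel (about `+(3/2) kT log 2` from the translations alone when
the restraint is fit to the bound ensemble, i.e. more than half a
kcal/mol), and it would treat complex-trajectory frames as samples of a
restrained state they were not drawn from. The convention used here is
validated empirically: on the exactly solvable toy systems below, the
full pipeline agrees with deterministic quadrature within its standard
error (the headline property test of the package). Note that the
restraint parameters are fit *from* the complex trajectory, but once
fixed they merely define the intermediate states; any restraint yields an
unbiased cycle, and its quality only affects variance through
phase-space overlap.

Complex frames are evaluated in the conditional state with the same
clash indicator used by the filter (`u_rc = +Inf` for a frame violating
a cutoff), which MBAR handles as a zero-support sample.

## The restraint: Gaussian translations, Bingham rotations

`U_zeta(zeta)/kBT = (1/2) (t - mu)' Sigma^-1 (t - mu) - q' M Z M' q`.

Translations are Gaussian with the sample mean and covariance of the
dominant pose mode. Rotations use the Bingham distribution, the
Gaussian analogue on the unit-quaternion sphere S^3: antipodally
symmetric (so `q` and `-q`, the same physical rotation, are equivalent),
with orthogonal axes `M` and diagonal concentrations `Z`. Conventions
fixed once, package-wide:

* quaternions are scalar-first, canonicalized to the nonnegative-scalar
  hemisphere (ties broken by the first nonzero component);
* rotations act about the centroid of the reference-pose ligand, which
  decouples `t` from `q`;
* the gauge `max(Z) = 0` (the Bingham density is invariant to adding a
  constant to all concentrations), making the mode energy exactly zero;
* all quaternion integrals run over the full sphere S^3 with the uniform
  density on S^3 as the unrestrained reference, so the double-cover
  factor of two cancels identically between the restrained and
  unrestrained rotational volumes.

The restraint's log partition function splits into a closed-form
translational factor `log[(2 pi)^{3/2} |Sigma|^{1/2}]` and the Bingham
normalization `C(Z) = \int_{S^3} exp(sum_i z_i q_i^2) dS`. The azimuthal
integral of `C(Z)` is analytic (a Bessel `I_0`), and the remaining 2-D
integral is evaluated by tensor Gauss-Legendre quadrature with order
doubling to a relative tolerance of 1e-8; with the gauge `z <= 0` the
log-space integrand cannot overflow. The release leg is then

`dG(0 -> r) = -kT [ log(Z_t / V0) + log(C(Z) / 2 pi^2) ]`, `V0 = 1660 A^3`.

Fitting inverts the eigenvalues of the antipodally symmetrized scatter
`E[q q']` by maximum likelihood (concave in `Z`; solved by L-BFGS-B with
quadrature gradients to 1e-8, concentrations floored at -5000). Sampling
uses the standard angular-central-Gaussian rejection envelope, which has
bounded acceptance for all concentrations; translation covariances are
floored at 1e-4 A^2 so that rigid poses in short trajectories cannot
collapse `Sigma`.

### Pose mode selection

Bound ensembles can be multimodal (distinct binding orientations). The
restraint is fit to the most populated mode, found by mean-shift in the
7-dimensional `(t, canonical q)` embedding. Two numerical choices matter
and were made deliberately:

* **Scaling.** The three translation components share units and the four
  quaternion components share units, so each *group* is scaled by its
  pooled RMS spread. Per-dimension standardization would divide a
  well-separated axis by its between-mode variance and blur genuinely
  distinct modes into each other.
* **Bandwidth.** The default is `1.25 x n^{-1/11}` on the scaled
  embedding. Scott's rule proper (factor 1.0) targets integrated
  density-estimation error and, in seven dimensions, fragments even a
  unimodal Gaussian cloud into dozens of spurious local maxima; the 1.25
  factor removes nearly all of that fragmentation while still resolving
  modes separated by about two pooled standard deviations (verified on
  unimodal, 80/20 bimodal, and double-well reference cases in the test
  suite). Points are assigned to modes by basin of attraction (running
  the mean-shift iteration from every sample), not by nearest-center
  distance, which misassigns outliers.

Complex frames outside the selected mode are *not* discarded: the
restraint energy reweights them in the MBAR leg, avoiding an arbitrary
hard cutoff.

## Clash filtering

Per-pair cutoffs `c_ij` solve `4 eps_ij [(sig_ij/d)^12 - (sig_ij/d)^6] =
E_clash` on the repulsive branch, with Lorentz-Berthelot combination and
`E_clash = 2` kcal/mol by default; the root is analytic in `(sig/d)^6`,
so it is exact to machine precision, and pairs with `eps = 0` (some
force-field hydrogens) have no LJ interaction and are exempt. Poses are
tested against a uniform cell grid (cell edge = largest cutoff) built
once per receptor frame, so each ligand atom touches a constant-size
neighborhood; the C++ filter is verified against a brute-force
`O(P x L)` double loop on random instances. Intra-receptor and
intra-ligand contacts are never retested: those frames are already
Boltzmann samples of their own potentials, and the conditional state
conditions only on receptor-ligand pairs.

The pose budget follows `N_zeta = max(1, floor(N_target / (N_P N_L)))`
with `N_target = 1e9` by default (the method's standard protocol). Pose
draws are seeded per zeta-block so that surviving poses can be
regenerated instead of stored, keeping memory bounded; filtering is
performed in pocket-aligned coordinates (rigid-motion invariant), while
energies are evaluated in each receptor frame's own lab frame via the
inverse pocket alignment, so the restraint is defined relative to the
pocket rather than the laboratory.

## Trajectory reduction

Each input ensemble is reduced to effectively independent frames before
use: an equilibration prefix is chosen per independent run by maximizing
`(N - t0)/g` over a geometric grid of candidate burn-ins (with a
configurable floor), where the statistical inefficiency `g` is computed
from the integrated autocorrelation of an observable, truncated at the
first non-positive autocorrelation. The observable is the backend
potential energy when a backend is attached, else the first principal
component of the coordinates. Thinning uses `round(g)` (ceiling would
silently halve an uncorrelated series whose `g` is estimated at, say,
1.05). A constant observable is defined to have `g = 1`: autocorrelation
is undefined there and keeping all data is the conservative choice.
Runs pooled from independent simulations are decorrelated separately and
then re-pooled. Both MBAR sample sets are capped at `n_s = 5000` frames
(subsampled uniformly, seeded) before any energy evaluation, since
energy calls dominate cost.

## Toy systems and what they do (and do not) show

The package ships generators for host-guest toys whose exact binding
free energy is computable by deterministic quadrature: a cage of
harmonically tethered host atoms around a site that acts on the rigid
guest's pose -- `harmonic` (quadratic trap), `harmonic_lj` (trap plus a
central soft-core LJ sphere giving an anharmonic radial shell),
`double_well` (quartic double well along z, a bimodal bound ensemble),
and `box` (flat, entropy-free well used for the end-state-baseline
contrast) -- plus an orientational well `kappa (1 - (q . q0)^2)`, which
is exactly a Bingham-shaped density, and per-atom LJ parameters that
drive the clash filter. Because the site potential acts on the pose and
the tethers are independent of the guest, the host and guest internal
coordinates cancel exactly between bound and unbound states, and the
exact answer reduces to 1-D quadratures (relative tolerance 1e-9). All
ensembles are sampled exactly (Gaussians, uniform rotations, 1-D
inverse-CDF with within-cell jitter on an 8192-point grid, and rejection
sampling for orientations), so there is no MD error to confound the
estimator check.

These toys exercise every pipeline stage with nontrivial work --
restraint fitting on noisy multimodal poses, clash filtering with real
LJ cutoffs against fluctuating cage atoms, anharmonic and bimodal MBAR
reweighting -- but they are not proteins: the guest is rigid, the site
energy is low-dimensional by construction (that is what makes the ground
truth exact; in `harmonic_lj` the LJ term acts on the centroid distance
for the same reason, while the per-atom LJ parameters still drive the
steric filter), the host cannot undergo induced fit, and the "solvent"
is implicit in the potentials. Passing the exactness tests therefore
validates the *estimator* -- the cycle bookkeeping, the restraint
analytics, the filter counting, and the reweighting -- not the physical
accuracy of any force field or solvent model on real complexes.

Study sizes used by the validation suite and the acceptance script:
10,000 frames per end-state ensemble, combinatorial budget
`N_target = 4e5` pairs with 400-frame caps on the receptor and ligand
sets entering composition, and `n_s = 5000` per MBAR state. At these
sizes the total standard error is well under 0.1 kcal/mol on all three
toys and each system completes in a few minutes on one core.

## Error model

The release leg is analytic (zero statistical error given the fitted
restraint). The filter leg carries a binomial delta-method error on
`log(alpha)`; combinatorial pose tests share receptor frames and zeta
draws, so this is a lower bound used as stated. The MBAR leg uses the
maximum-likelihood (Bennett/Fermi-function) asymptotic variance
`1/sum(p(1-p)) - 1/n_A - 1/n_B`, which is exactly zero for identical
states. Legs combine in quadrature. The two-state overlap diagnostic is
one minus the second eigenvalue of the row-stochastic MBAR overlap
matrix (1 = identical states, 0 = disjoint); values below 0.01 attach a
warning rather than an error -- low overlap is a property of the system
worth surfacing, and the corresponding structural failure (`alpha = 0`,
e.g. a binding site that closed during the receptor-only run) is a
classed error that the multi-pose driver reports as an exclusion rather
than imputing a value.

## Degenerate inputs and edge policies

* Ligands with fewer than three non-collinear atoms have no resolvable
  rotation: pose extraction returns a translation-only transform and the
  rotational restraint is inactive (`Z = 0`), which contributes exactly
  zero to both the release leg and the sampled ensembles -- consistent by
  construction. A genuinely rank-deficient quaternion scatter from
  resolvable rotations is an error.
* Ligand symmetry: element-preserving graph automorphisms (capped at
  10,000, with a truncation warning) are minimized over during pose
  extraction, so symmetric poses do not masquerade as distinct modes.
  RMSD ties between permutations resolve to the lexicographically
  smallest permutation for determinism.
* `alpha = 1` (no possible clash) gives a filter leg of exactly zero;
  `alpha = 0` is the structured no-overlap failure described above.
* All randomness flows from one integer seed through a deterministic
  seed-derivation chain; reports are byte-identical across reruns of the
  same configuration and contain no timestamp unless requested.

## Interfaces

`dbfe()` is the fitting function and returns a classed object with
`print`, `summary`, `coef`, `confint`, `plot` (pose cloud and state
overlap), and `simulate` (draws from the fitted restraint) methods;
`predict` and `residuals` have no meaning for a free-energy estimate and
are deliberately absent. `dbfe_run()` drives a run from a YAML/list
configuration, `dbfe_multipose()` Boltzmann-combines poses, and a thin
`inst/exec/dbfe` script exposes `run`, `toy`, and `combine` subcommands.
Restraints and reports serialize to JSON for audit and reuse. File
formats: PDB (CONECT honored) and SDF topologies with JSON Lennard-Jones
sidecars (these formats do not carry LJ parameters), a documented
plain-text multi-frame XYZ trajectory format, and binary DCD through an
adapter. MOL2 is not read; convert ligands to SDF.

## Known limitations

* The filter-leg standard error ignores the dependence structure of the
  combinatorial pose tests (documented above).
* The Bingham normalization quadrature is tested to concentrations of
  order 1e3; restraints tighter than that trip the concentration floor.
* MM/GBSA-style baselines are single-trajectory by design (components
  extracted from complex frames); no entropy correction is attempted --
  that contrast with the full estimator is demonstrated quantitatively
  on the toys in the test suite.
* Real-MD energy backends are a contract (`evaluate(topology, coords)`),
  not an implementation: production MD, force-field assignment, and
  explicit solvent are out of scope.
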