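# dbfe — Direct Binding Free Energy estimation from end-state ensembles

`dbfe` computes absolute binding free energies (ΔG of P + L → PL at
standard state) from **three plain molecular-dynamics ensembles in
implicit solvent** — receptor-only, ligand-only, and complex — with *no
alchemical intermediate states*. It is aimed at molecular-modelling and
virtual-screening workflows where the receptor and ligand simulations
can be precomputed and amortized across many candidate compounds, so
the per-ligand cost reduces to a single short complex simulation.

## The estimator

A direct two-state estimate between the decoupled potential
`U₀ = U_P + U_L` and the coupled `U₁ = U_PL` fails for lack of
phase-space overlap: almost any placement of a ligand sample into a
receptor sample clashes sterically. `dbfe` restores overlap in three
exactly telescoping legs:

1. **Restraint release** `ΔG(0→r) = −kT [ln(Z_t/V°) + ln(Z_q/2π²)]`.
   The ligand's rigid-body pose ζ = (t, q) — translation plus rotation
   quaternion relative to a pocket-aligned reference frame — is
   restrained by `U_ζ/kT = ½(t−μ)ᵀΣ⁻¹(t−μ) − qᵀMZMᵀq`: Gaussian
   translations and a Bingham (Gaussian-on-S³) rotation density, fit to
   the largest pose mode of the complex trajectory (mean-shift
   clustering, symmetry-aware pose extraction). This leg is analytic:
   `Z_t = (2π)^{3/2}|Σ|^{1/2}`, `Z_q` the Bingham normalization
   (quadrature to 1e-8), `V° = 1660 Å³`.
2. **Combinatorial clash filter** `ΔG(r→rc) = −kT ln α`. Because
   `U_r = U_P + U_L + U_ζ` has no cross terms, any (receptor frame,
   ligand conformation, restraint draw) triple is a valid sample of its
   Boltzmann distribution. Out of `N_P·N_L·N_ζ` composed samples
   (`N_ζ = N_target/(N_P N_L)`), a spatial-index filter keeps the
   fraction α with all receptor–ligand atom pairs beyond their
   Lennard-Jones clash cutoffs `c_ij` (the distance where the LJ pair
   energy equals 2 kcal/mol on the repulsive branch).
3. **One MBAR step** `ΔG(rc→1)`: a two-state MBAR/BAR estimate between
   the clash-free restrained decoupled ensemble and the physical
   complex ensemble (≤ 5000 frames per state), with an asymptotic
   standard error and an overlap diagnostic.

The sum telescopes exactly to `−kT ln(Z₁/Z₀)`, the standard-state
binding free energy. An MM/GBSA-style single-trajectory baseline and
percentile-bootstrap benchmark metrics (RMSE, Pearson r, Spearman ρ)
are included for comparison studies.

Everything is validated against ground truth: the package ships toy
host–guest systems (harmonic, anharmonic LJ-shell, and double-well
binding sites with orientational wells) whose ensembles are sampled
exactly and whose ΔG is computed independently by deterministic
quadrature; the full pipeline reproduces those values within its
reported standard error.

## Worked example

Fit the estimator on a toy host–guest complex with an anharmonic
(Lennard-Jones shell) binding site, 2000 frames per ensemble:

```r
library(dbfe)
spec     <- make_harmonic_host_guest(kind = "harmonic_lj", seed = 5)
receptor <- direct_boltzmann_sample(spec, "receptor", 2000, seed = 101)
ligand   <- direct_boltzmann_sample(spec, "ligand",   2000, seed = 102)
complx   <- direct_boltzmann_sample(spec, "complex",  2000, seed = 103)

fit <- dbfe(receptor, ligand, complx, make_toy_backend(spec),
            n_target = 2e5, n_s = 2000, n_receptor_max = 200,
            n_ligand_max = 200, seed = 1)
summary(fit)
```

```
Direct binding free energy estimate
  dG(0->r)   restraint release :    3.919 kcal/mol
  dG(r->rc)  clash filter      :    0.700 kcal/mol (alpha = 0.309)
  dG(rc->1)  MBAR              :   -3.301 kcal/mol
  dG(binding)                  :    1.318 +/- 0.069 kcal/mol

Samples: N_P = 200 receptor frames, N_L = 200 ligand confs, N_zeta = 5
Pairs tested: 2e+05, clash-free fraction alpha = 0.309
Pose modes: 9 (restraint fit on 724 frames of 2000)
MBAR: 2000 decoupled + 2000 complex samples, overlap = 0.0688
```

Reading the output: imposing the fitted pose restraint on a free ligand
at 1 M costs +3.92 kcal/mol; conditioning the composed decoupled
ensemble on clash-free configurations (31% survive) costs +0.70; the
reweighting into the physical complex returns −3.30; the binding free
energy is their sum, **+1.32 ± 0.07 kcal/mol** (an unfavorable binder —
the LJ shell makes this site mostly repulsive). The independent ground
truth for this system is

```r
exact_delta_g_quadrature(spec)   # 1.344 kcal/mol
confint(fit)                     # dg_total: [1.182, 1.454]
```

so the estimate agrees with the exact answer well within its confidence
interval. `plot(fit)` shows the pose-translation cloud with the
restraint mode and the two-state overlap histograms; `simulate(fit, n)`
draws poses from the fitted restraint; `coef(fit)` returns the three
legs and the total.

Real systems use the same interface with file-based inputs — PDB
(CONECT honored) / SDF topologies plus JSON Lennard-Jones sidecars,
plain-text XYZ or binary DCD trajectories — through `read_topology()`,
`read_trajectory()` and a user-supplied energy backend
(`evaluate(topology, coords)` in kcal/mol, implicit solvent included).
A thin CLI wraps the same functions:

```sh
inst/exec/dbfe run --config cfg.yaml         # full pipeline from YAML
inst/exec/dbfe toy --preset harmonic --out fixtures/
inst/exec/dbfe combine pose1.json pose2.json # Boltzmann-weighted poses
```

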