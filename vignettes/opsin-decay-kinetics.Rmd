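---
title: "Models and methods: quantifying visual-opsin active-state decay"
author: "opsindecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying visual-opsin active-state decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsindecay)
```

## The scientific problem

Visual opsins are light-activated GPCRs. Photoisomerisation of their retinal
chromophore produces the signalling meta II (MII) state, which decays when the
retinal Schiff-base linkage is hydrolysed and the all-*trans*-retinal agonist
leaves the binding pocket. Cone opsins decay orders of magnitude faster than
rhodopsin — wild-type human green cone opsin loses its active state with a
half-life of tens of seconds where rhodopsin takes tens of minutes — and this
lifetime difference, rather than any difference in G-protein coupling, limits
how much transducin (Gt) a cone opsin can activate. This package implements
the analysis chain used to quantify that picture: fluorescence-trace kinetics,
transition-state thermodynamics, solvent-isotope mechanism classification, a
pool-activation model for Gt, and structure-based cavity volumetrics.

Every stage has a seeded synthetic-data generator, so the full chain is
testable end to end without any external data.

## Retinal-release kinetics

The retinal-release assay follows intrinsic tryptophan fluorescence at
330 nm: release of retinal from the pocket de-quenches Trp residues and the
signal rises. The model is a flat dark baseline before light onset at
$t_{h\nu}$ followed by a monoexponential rise,

$$\Delta F(t) = A\,\bigl(1 - e^{-k\,(t - t_{h\nu})}\bigr), \qquad
t_{1/2} = \ln 2 / k .$$

`subtract_dark_baseline()` averages the pre-onset samples and subtracts that
level; `fit_monoexponential()` fits $A$ and $k$ by damped
(Levenberg–Marquardt) least squares via minpack.lm, with analytic starting
values ($A_0$ from the maximum of $\Delta F$; $k_0$ from a log-linear
regression of $\log(1 - \Delta F/A_0)$ against $t - t_{h\nu}$, with $A_0$
inflated by 5% so the logarithm stays defined under noise). Choices worth
stating:

* **$t_{h\nu}$ is metadata, never fitted.** The experimental 2-s irradiation
  is treated as instantaneous because it is short even against the fastest
  half-life modelled (18 s).
* **Pure monoexponential, no drift term.** Real control traces can drift
  slowly after the plateau; the fit deliberately ignores drift and reports
  the RMSE so drift is visible rather than absorbed.
* **Failure is flagged, not thrown.** Non-convergence or a nonpositive rate
  returns `converged = FALSE` with `NA` parameters, so batch runs survive
  degenerate traces (e.g. a flat trace has no identifiable rate).
* Half-life is reported alongside the rate everywhere, because half-lives
  are what the assay literature quotes.

The shipped presets (`opsin_presets()`) encode the measured mean half-lives:
Rho_WT 2188 s, GCO_WT 18 s, GCO_E102Q 139 s at 9–10 °C, plus the H2O/D2O
pairs GCO_WT 23.3/35.6 s and GCO_E102Q 131.6/268.3 s at 9 °C. The source
reports the first three at "10 °C" in a figure and "9 °C" in the text; the
presets record that discrepancy in a `note` field rather than resolving it.
Reported half-life standard deviations of order $10^{-3}$ s on n = 3
replicates are implausibly tight, so presets store means only. The apparent
initial rate of a trace (`initial_rate()`) is an ordinary least-squares slope
over the first 30 s after onset, the convention used for Gt-assay
comparisons.

### Noise model and what the generator does not emulate

`generate_release_trace()` adds i.i.d. Gaussian noise on fluorescence — the
simplest model consistent with photon counting at high signal. It does not
simulate photobleaching, lamp drift, shot-noise scaling, or the 480-nm side
species some mutants show. Parameter-recovery results on synthetic traces
therefore demonstrate estimator correctness and calibration, not robustness
to every artefact of real fluorimeter data. At 2% noise, 100 seeded
GCO_WT traces (0–120 s, 0.5-s sampling) give a median recovered half-life
within 2% of truth with ~95% CI coverage (see the test suite).

## Transition-state thermodynamics

Rates measured across temperature are fit two ways (`arrhenius_fit()`,
`eyring_fit()`), both as ordinary least squares on linearised forms:

$$\ln k = \ln A - \frac{E_a}{R T}, \qquad
\ln\frac{k}{T} = \ln\frac{k_B}{h} + \frac{\Delta S^\ddagger}{R'}
- \frac{\Delta H^\ddagger}{R T},$$

with $\Delta G^\ddagger = \Delta H^\ddagger - T\,\Delta S^\ddagger$ evaluated
at 298 K by `delta_g()`. Units follow biochemistry convention and are named
in every output: kcal/mol for $E_a$, $\Delta H^\ddagger$,
$\Delta G^\ddagger$; cal/(mol K) for $\Delta S^\ddagger$
($R = 1.9872\times10^{-3}$ kcal/(mol K), $R' = 1.9872$ cal/(mol K); exact SI
$k_B$ and $h$; transmission coefficient fixed at 1). Standard errors come
from the regression covariance. Fits are unweighted by default — the
measurement protocol behind the data does not state a weighting — with an
optional `weights` argument (e.g. $1/\mathrm{se}^2$) for replicate-level
work; per-temperature means are the default mode since the published points
are replicate averages. For any noiseless Eyring-generated series the two
analyses are linked by the condensed-phase identity
$E_a \approx \Delta H^\ddagger + R\bar T$, which the tests verify to
0.1 kcal/mol.

Multiplicative (log-normal) noise is used for synthetic rate series because
rates are positive and their errors scale with magnitude.

## Solvent isotope effects and the proton inventory

The solvent KIE is $k_{\mathrm{H_2O}}/k_{\mathrm{D_2O}}$, identically
$t_{1/2}^{\mathrm{D_2O}}/t_{1/2}^{\mathrm{H_2O}}$ for first-order decay;
`solvent_kie()` accepts both parameterisations. Note that a KIE quoted as a
mean of per-replicate ratios need not equal the ratio of mean half-lives
(for the GCO_WT pair, 35.6/23.3 = 1.528 while the published summary rounds
to ~1.54); the package computes the ratio of whatever values it is given and
asserts nothing about which estimator a summary number used.

The proton inventory measures the rate at intermediate D2O atom fractions
$n$ and fits the Gross–Butler relation with ground-state fractionation
factors fixed at 1 (no basis exists for fitting them):

$$\frac{k_n}{k_0} = \prod_{j=1}^{m} \bigl(1 - n + n\,\phi_j\bigr).$$

For $m = 1$ this is exactly linear in $n$ with slope $\phi - 1$; for $m = 2$
it is quadratic. Both models are linear after the change of variables
$s = \phi_1 + \phi_2$, $p = \phi_1\phi_2$, so `gross_butler_fit()` solves
them in closed form; if the unconstrained quadratic has no valid
factorisation ($s^2 < 4p$), an equal-$\phi$ fit is substituted and flagged.
When raw rates are supplied, $k_0$ is fitted jointly, normalising against
the fitted intercept rather than a single reference measurement (which would
give one point undue leverage). Only $m \in \{1, 2\}$ are supported: with
the ≤7 D2O fractions of a practical inventory, higher site counts are not
identifiable, and the scientific question is binary (single-site vs
multisite transfer). `select_inventory_model()` compares the two by the
extra-sum-of-squares F-test at $\alpha = 0.05$, the simpler model winning
ties — a linear inventory indicates one transferred proton in the
rate-limiting Schiff-base hydrolysis step, curvature indicates several. At
1% noise on 7 fractions this separates $\phi = 0.65$ single-site from
$\phi = (0.5, 0.5)$ two-site data in ≥90% of seeded runs.

## Transducin pool activation

The Gt model couples receptor decay to pseudo-second-order pool activation:

$$\frac{dR^*}{dt} = -k_{\mathrm{decay}} R^*, \qquad
\frac{dG^*}{dt} = k_{\mathrm{act}}\, R^* \,(G_{\mathrm{tot}} - G^*),$$

with the closed-form solution

$$G^*(t) = G_{\mathrm{tot}}\Bigl[1 -
\exp\Bigl(-\tfrac{k_{\mathrm{act}} R_0}{k_{\mathrm{decay}}}
\bigl(1 - e^{-k_{\mathrm{decay}} t}\bigr)\Bigr)\Bigr],$$

so total activation $G_{\mathrm{tot}}(1 - e^{-k_{\mathrm{act}}
R_0/k_{\mathrm{decay}}})$ is strictly decreasing in the decay rate: the
model-level statement of the central finding that active-state lifetime, not
coupling, sets how much of the Gt pool is activated. The closed form is
cross-checked against numerical ODE integration (deSolve) in the tests. The
model deliberately omits MII stabilisation by bound Gt, a separate
GTPγS-binding step, and Michaelis–Menten saturation — at the 20–40× Gt
excess of the assay (15 nM receptor, 300–600 nM Gt) the pseudo-second-order
regime is the identifiable one, and the lifetime-vs-total-activation
argument needs nothing more. Whether observed "similar initial rates"
reflect receptor- or Gt-limited kinetics cannot be decided from summary
data; both regimes are reachable through the parameters. Fluorescence is a
linear combination of activated Gt and released retinal with separate
coefficients, since assay controls show both contribute.

## Cavity volumes and hydration capacity

`detect_cavities()` implements dual-probe grid cavity detection in the
KVfinder style: a lattice (default spacing 0.6 Å) covers the structure plus
padding; points within (vdW + 1.4 Å) of any atom are closed to the water
probe; the large probe (4.0 Å) is rolled in from bulk solvent by
flood-filling its allowed centre positions from the grid boundary and
sweeping its volume. Cavity points are water-accessible points the swept
large probe cannot reach — note this is the interior-filling definition:
a simple distance threshold to the large probe would hollow out any cavity
wider than the probe and underestimates the toy-shell volume by ~24%.
Components are 26-connected; those touching the grid boundary or smaller
than 5 ų are discarded. Defaults (0.6/1.4/4.0/5 ų) are the established
values of this method family, configurable and echoed in every result. The
probe sweep composes large dilations from ≤4.5-voxel passes (Minkowski
sums), a ≤1-voxel rounding per pass that is negligible against the 10%
grid-method tolerance.

vdW radii are Bondi-style (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
H 1.10 Å); unknown elements get 1.7 Å with a warning; hydrogens are dropped
by default since cryo-EM models are hydrogen-free.

`cavity_report()` removes the ligand from the occluder set, selects the
cavity containing the ligand centroid (not simply the largest — the
quantity of interest is the ligand-free cavity), subtracts the ligand's own
vdW volume (`ligand_volume()`, fine-grid union of spheres at 0.25 Å), and
converts the net volume to a water capacity. `water_capacity()` uses
**floor**, never rounding — the only convention consistent with both
published reference conversions (1454.3 ų → 48 waters from 48.72;
842.4 ų → 28 from 28.22) — at the standard number density
3.35 × 10⁻² H₂O/ų. That constant follows from 1 g/mL with the conventional
round molar mass 18.0 g/mol, which `h2o_per_cubic_angstrom()` uses as its
default; the exact molar mass 18.015 g/mol gives 3.343 × 10⁻² (0.2% lower)
and is available through the `molar_mass` argument. Where cavity-size
ratios are quoted, note that gross and net volumes give different ratios
(for the published pair, 1.73 net vs ~1.5 gross); both volumes are always
reported so either ratio can be formed.

Toy validation structures (`generate_toy_structure()`) are Fibonacci-lattice
spherical shells whose enclosed probe-accessible volume is known
analytically and independently checkable by a fine-grid flood-fill oracle;
the tests require agreement within 10% at 0.2-Å oracle spacing, <5% change
under grid halving, and <5% change under rigid motion. Checks against
deposited cryo-EM structures require downloads and a specific
KVfinder/ChimeraX configuration; they are intentionally out of the default
test scope, and per-helix RMSD residue ranges for such comparisons must be
supplied by the user (`kabsch_rmsd(selections = )`), since no standard set
exists.

## Superposition

`kabsch_rmsd()` is the standard SVD construction with reflection correction
(rotation determinant +1), pairing atoms by (chain, residue number, atom
name) unless an explicit pairing is given, with residue numbering taken
verbatim from the input. Per-selection (e.g. per-helix) RMSDs are read out
in the single global superposition frame — the reporting convention of
interactive structure viewers — not re-fitted per selection. Collinear or
coincident paired sets leave the rotation underdetermined and are flagged
`degenerate`. The implementation is cross-checked in the tests against
bio3d's independent superposition and against a rotation-grid brute-force
oracle.

## Randomness, determinism and numerical tolerances

All stochastic generators draw through one injectable seeded generator that
saves and restores the caller's RNG state, so identical seeds give
bitwise-identical outputs and no package function perturbs global RNG
state. Noiseless generator outputs satisfy their defining formulas to
≤10⁻¹⁰ relative error, and each noiseless dataset is inverted by its fitting
stage to the generating parameters (10⁻⁶ relative for the nonlinear trace
fit, 10⁻⁹ for the linearised thermodynamic fits, machine precision for the
closed-form inventory fits).

Problem sizes used by the test and acceptance runs — 300–500-point traces,
100-seed noise sweeps, 50-seed model-selection sweeps, 500–1000-atom toy
shells with a 0.2-Å oracle grid — were chosen as the smallest sizes at which
the statistical criteria are stable, and run in well under half an hour on a
single CPU.

## Known limitations

* The monoexponential model ignores slow drift and any second kinetic
  component (e.g. 480-nm photointermediates); RMSE is the drift dial.
* Ground-state fractionation factors are fixed at 1; D2O viscosity effects
  and equilibrium isotope effects are not modelled.
* The Gt model fits no real traces (none are deposited); it is a
  demonstration and hypothesis-exploration model.
* Grid cavity volumes are method- and parameter-dependent; agreement with
  other tools' absolute volumes should be expected only to ~10–20%.
* The synthetic generators emulate the study conditions, not every artefact
  of real instruments; passing tests certify the estimators, not the
  instruments.
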