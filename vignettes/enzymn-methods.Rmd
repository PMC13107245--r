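---
title: "Methods: toy multiscale models of enzyme–Mn synergistic catalysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: toy multiscale models of enzyme-Mn synergistic catalysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzymn)
```

# The problem this package models

Hybrid catalysts that couple an enzyme active site (here, a CALB-like
triad of His, Ser and Asp residues) with a Mn^2+^ center lower the
activation energy of C–N bond-forming reactions such as quinazolinone
synthesis well below what either component achieves alone. Studying that
synergy computationally involves a stack of standard machinery: geometry
and coordination analysis of the metal site, a molecular-mechanics force
field, thermostatted/barostatted dynamics, transition-state search with
vibrational validation, umbrella-sampling free energies, hydrogen-bond
statistics, and table-level summaries over a substrate series
(QD-01…QD-15).

`enzymn` implements that entire stack at desk scale, on *toy* systems and
analytic surfaces with planted, machine-readable ground truth. The point
is not to replace electronic-structure calculations — no quantum
chemistry is performed anywhere in the package — but to make every stage
of the workflow testable: each generator states a world, and each method
is scored against that world's truth record.

# Models and conventions

## Unit system

A single coherent system: Å, fs, amu, K, kcal/mol, elementary charge
(`unit_constants()`). Derived constants:

* k~B~ = 1.987204×10^−3^ kcal/(mol·K);
* 1/(4πε~0~) = 332.0637 kcal·Å/(mol·e²);
* 1 kcal/(mol·Å·amu) = 4.184×10^−4^ Å/fs²;
* 1 eV = 23.0609 kcal/mol;
* the vibrational conversion 108.5915 cm^−1^ per √(kcal/(mol·Å²·amu)),
  derived from CODATA values (note that the familiar constant 1302.8
  belongs to force constants in mdyn/Å, not this unit system).

## Coordination geometry and charge polarization

The Mn–O shell is described by two smooth descriptors:

* **Coordination number**: each ligand contributes
  exp(−(R~i~−R~0~)²/(2σ²)) with R~0~ = 2.08 Å and σ = 0.05 Å by default.
  A literal sum of −(R~i~−R~0~)²/(2σ²) terms (without the exponential)
  is unbounded below and cannot produce counts near the ligand number,
  so the Gaussian-smoothed form is used. One consequence worth knowing:
  for a shell whose *thermal spread equals σ*, the expected per-ligand
  contribution is 1/√2 ≈ 0.71, so a 4-coordinate site at thermal
  equilibrium reads ≈ 2.8, not 4.0; the count reaches the integer value
  only as the geometry approaches ideal.
* **Effective charge**: Q = Σ Z~i~ e^(−k·r~i~)/(4πε~0~ r~i~) with
  attenuation k = 1.2 Å^−1^. The screened-potential kernel makes the
  absolute units conventional; the package relies only on its internal
  properties (linearity in Z~i~, rigid-motion invariance, distance
  decay), all of which are property-tested.

## Toy force field

Harmonic terms carry **no ½ factor** (CHARMM convention):
E = ΣK~b~(r−r~0~)² + ΣK~θ~(θ−θ~0~)² + ΣK~φ~(1+cos(nφ−δ)) +
Σ(A/r¹² − B/r⁶) + Coulomb. Keep that in mind when transferring force
constants — a bond of constant K~b~ oscillates at ω = √(2K~b~/m), not
√(K~b~/m). Nonbonded terms exclude 1-2 and 1-3 pairs (from the bond
graph) and keep 1-4 pairs at full strength; the exclusion rule is
configurable. Bond, angle, Lennard-Jones and Coulomb forces are
analytic; the dihedral contribution uses a central finite difference
confined to its four atoms (cheap, and verified against the full
finite-difference oracle in the tests).

## Dynamics

Position Verlet: r(t+Δt) = 2r(t) − r(t−Δt) + (F/m)Δt², default Δt = 2 fs.
The integrator carries no velocities; the thermostat's instantaneous
temperature uses the backward difference (r(t)−r(t−Δt))/Δt with 3N−3
degrees of freedom, and rescaling acts by moving the previous-position
slot. Recorded energies use the *central* difference
(r(t+Δt)−r(t−Δt))/(2Δt) via a one-step look-ahead — the backward
estimator would pollute conserved-energy monitoring with an O(Δt)
artifact. Temperature and pressure coupling are Berendsen-type weak
relaxations (for a force-free gas the temperature relaxation
T−T~target~ ∝ exp(−t/τ~T~) is exact per step, which the tests exploit);
the barostat is isotropic — toy systems never need the full cell-matrix
form. The published production protocol (5000-step steepest-descent
minimisation, 10 ns NVT, 20 ns NPT, 100 ns production) is encoded as
`md_preset("production")` but exercised in tests at ≤10⁴ steps.

## Transition-state search

The band force is the *plain* elastic form
F~i~ = −∇E(R~i~) + κ(R~i+1~ − 2R~i~ + R~i−1~) — faithful to the
workflow being modelled; improved-tangent projection is a known
extension, not implemented. The climbing image activates once the plain
band's maximum interior force falls below 10× the convergence
tolerance; it receives the true force with the component along the
chord tangent (R~i+1~ − R~i−1~) inverted and no spring force, ties
broken toward the lowest index. Defaults: 10 images, κ = 5.0 eV/Å²,
max-force tolerance 0.05 eV/Å and RMS tolerance 0.02 eV/Å, all
converted once to kcal/mol units. The optimizer is damped steepest
descent with adaptive step halving; no optimizer is prescribed by the
protocol being modelled, and this is the minimal robust choice.

Saddle validation follows the standard recipe: a symmetric
central-difference Hessian (default step 10^−4^), mass-weighted normal
modes, the requirement of *exactly one* imaginary frequency whose mode
overlaps the declared reaction coordinate (squared-component overlap
≥ 0.5 by default), and steepest-descent paths launched from saddle ±
ε·mode that must terminate in the flanking minima. The reduced mass of
a mode with normalized mass-weighted eigenvector w is 1/Σ(w~i~²/m~i~).

## Umbrella sampling and WHAM

Windows are harmonic biases ½k(R−R~i~)². The default sampler is
Metropolis-adjusted Langevin (MALA): the overdamped-Langevin proposal is
accepted/rejected so the stationary distribution is *exactly* Boltzmann,
making WHAM accuracy a question of statistics and binning only.
Unadjusted Langevin and random-walk Metropolis are provided as
alternatives (the latter for non-differentiable surfaces). The default
mobility step is 0.5/k, scaling the proposal to the biased-well width
while keeping successive samples nearly decorrelated.

WHAM iterates the standard self-consistency (bias **subtracted** — only
this sign convention recovers a planted profile) on left-closed,
right-open bins, converging on the maximum relative change of the window
constants (default 10^−6^). Bins with fewer than `min_count = 5` total
samples are reported as `NA`: their inverse-bias-amplified shot noise
would otherwise capture the anchor (the profile minimum, fixed at 0) and
shift the entire curve. Adjacent windows with no shared occupied bins
are an error; shared-sample fractions below 5% draw a warning.

**Experiment design for barrier recovery.** The printed protocol pairs
20 windows with a bias constant of 1000 kcal/(mol·Å²) and a 0.1 Å
sampling interval. For a reaction coordinate spanning ~2 Å those numbers
are incompatible: at k = 1000 the biased windows have width
√(k~B~T/k) ≈ 0.024 Å against a 0.11 Å spacing — essentially zero
neighbour overlap — and a 0.1 Å histogram bin cannot resolve a 0.024 Å
window (measured: a +3.5 kcal/mol barrier artifact). The package
therefore keeps k = 1000 and bin 0.1 as the *defaults* as printed, but
the recovery experiments use k = 200 kcal/(mol·Å²) (window width ≈ half
the spacing, ~50% neighbour overlap) and 0.05 Å bins (resolving the
window width). A bin-width sweep confirmed the 0.1 Å bins alone carry a
systematic ≈ −0.1 kcal/mol barrier bias. The plausible reading is that
the printed 0.1 Å "sampling interval" is the window spacing
(20 × 0.1 Å = the 2 Å coordinate), not a histogram width.

Rates use k = A·exp(−ΔG‡/k~B~T) with A = k~B~T/h for the Eyring choice
(6.25×10¹² s^−1^ at 300 K). Measured proton-transfer rates of ~10³ s^−1^
at ~3.5 kcal/mol barriers imply an empirical prefactor ~7 orders of
magnitude below Eyring; the package reproduces such scales only through
an explicit user-supplied prefactor and makes no claim that they follow
from transition-state theory.

## Hydrogen bonds

A donor–hydrogen–acceptor triple is bonded when the donor–acceptor
distance is ≤ 3.5 Å **and** the D-H…A angle at the hydrogen
(180° = linear) is ≥ 150°, both boundaries inclusive. Occupancy is the
per-triple fraction of frames satisfying the criterion.

# The synthetic worlds

Each generator's defaults are the stated conditions of the system being
emulated, chosen once:

* `gen_mn_cluster()`: Mn at the origin, O ligands on tetrahedral (or
  octahedral/random) vertices, radial noise N(0, 0.05 Å) about 2.08 Å;
  charges +1.82 (Mn) and −0.40 (O), the transition-state NBO scale.
* `gen_double_well_surface()`: 1-D quartic a(x²−1)² + bx with exact
  closed-form truth, or a 2-D pair of Gaussian wells (width 0.5, centres
  ±1) whose truth saddle is found by a dense-grid minimax (union-find
  over cells activated in energy order — fully independent of the band
  method under test) plus Newton refinement. The grid default is
  301×301: pure-R union-find makes much finer grids (2001×2001)
  impractically slow, and at 301² the grid saddle is already within
  10^−3^ of the refined value on these smooth surfaces.
* `gen_hbond_trajectory()`: per frame and triple, a Bernoulli draw at
  the planted occupancy selects a bonded geometry (distance ≈ 2.85 Å,
  angle ≈ 165°, always satisfying the criterion) or an unbonded one
  (distance pushed beyond 3.7 Å or angle below 140°, split at random so
  both rejection branches are exercised). The truth record carries both
  the planted probability and the realized fraction.
* `gen_substrate_series()`: enzyme-only barriers uniform on
  27.5–32.5 kcal/mol, metal-only effect 5.1 ± 0.2 kcal/mol, synergistic
  reduction fractions uniform on 0.32–0.41 (matching the printed
  32.6–40.9% spread), optional Gaussian noise.

What these worlds do **not** emulate: real protein structure and
flexibility, electronic polarization and charge transfer, explicit or
continuum solvent dynamics, anharmonic coupling between reaction and
bath coordinates, or correlated hydrogen-bond kinetics (frames are
independent draws). A green test therefore establishes that an
*estimator recovers what was planted* — not that the toy world is an
accurate model of CALB–Mn catalysis.

# Reference-table statistics

The printed reference tables for the QD substrate series ship as CSV
fixtures (`reference_table()`), and every derived cell is recomputed:
reduction percentages (rounded half away from zero to 1 decimal — R's
round-half-even does not reproduce the printed cells), absolute/relative
errors, IR deviations, synergy fractions and sensitivity ranges.
`consistency_report()` compares recomputed values with the printed ones
and flags four claims the tables themselves do not support:

1. the headline **36.5%** mean activation-energy reduction — the printed
   reduction column averages 36.9% (36.92 before rounding; the fully
   unrounded recomputed mean is 36.93%);
2. the **"approximately sevenfold"** cyclability improvement — no
   supporting table exists;
3. the synergy table's **"Average" row** (−15.3/−27.5) — inconsistent
   with its own columns' means (−15.2/−27.2);
4. the **1.0 kcal/mol** maximum functional sensitivity — the QD-07 row
   spans 1.1 kcal/mol.

These are flagged, never targeted: the package reports recomputed
values.

# The ten-step pipeline

The full workflow, at toy scale:

```{r pipeline, eval = FALSE}
sys <- read_pdb_coords("complex.pdb")                     # 1 load structure
mini <- minimize_sd(sys, params)                          # 2 minimise
solv <- born_solvation(solvation_parameters(78.39, 1, 2)) # 3 solvation
params <- force_field(...)                                # 4 parameters
model <- coordination_model(center, ligands)              # 5 active site
neb <- run_neb(reactant, product, surface, neb_settings())# 6 CI-NEB
traj <- run_md(mini$system, params, 5e3, seed = 1,
               temperature = 300,
               thermostat = thermostat_settings(300))     # 7 dynamics
wins <- lapply(umbrella_ladder(-1, 1, 20, k = 200),
               run_umbrella_window, surface = surface,
               n_steps = 5e4, seed = 1)                   # 8 umbrella
occ <- hbond_occupancy(traj, triples, hbond_criterion())  # 9 H-bonds
write_xyz_frames(traj, mini$system, "trajectory.xyz")     # 10 export
```

# Known limitations

* No electronic structure of any kind; activation energies exist in the
  package only as (a) printed reference data and (b) barriers of
  analytic toy surfaces.
* Plain-band NEB (no tangent projection) can corner-cut on strongly
  curved 2-D paths; the climbing image protects the saddle energy, which
  is the quantity the tests score.
* The Berendsen-type couplings do not sample canonical/isobaric
  ensembles exactly; they are used for relaxation, which is what the
  tests assert.
* WHAM uncertainties are the rough per-bin k~B~T/√n estimate, not a
  bootstrap.
* Non-periodic distance conventions only; the periodic box exists for
  the barostat's bookkeeping, not minimum-image energetics.
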