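# enzymn

Desk-scale, fully testable models of **enzyme–Mn²⁺ synergistic catalysis**:
the computational workflow used to study how a metal center embedded in an
enzyme active site (a CALB-like His/Ser/Asp triad) lowers the activation
energy of C–N bond-forming reactions such as quinazolinone synthesis. The
package is aimed at method developers and students who want every stage of
that multiscale workflow — geometry, force field, dynamics, transition-state
search, free energies, hydrogen bonds, table statistics — as small, seeded,
oracle-scored R functions rather than an opaque simulation stack.

No quantum chemistry is performed: toy systems and analytic surfaces with
*planted ground truth* stand in for the expensive layers, so each estimator
can be verified against what was planted.

## What's inside

| Stage | Core model | Functions |
|---|---|---|
| Metal site | Gaussian-smoothed coordination number `N = Σᵢ exp(−(Rᵢ−R₀)²/2σ²)` (R₀ = 2.08 Å, σ = 0.05 Å); screened charge `Q = Σᵢ Zᵢ e^{−kRᵢ}/(4πε₀Rᵢ)` | `coordination_number()`, `effective_charge()`, `bond_angle()`, `dihedral()` |
| Energetics | `E = ΣK_b(r−r₀)² + ΣK_θ(θ−θ₀)² + ΣK_φ(1+cos(nφ−δ)) + Σ(A/r¹²−B/r⁶)` + Coulomb (no ½ factors); Born solvation `−½(1−1/ε)q²/(4πε₀R_cav)`; synergy `E_syn = E_EMS − E_ES − E_MS + E_S` | `mm_total_energy()`, `mm_forces()`, `born_solvation()`, `synergy_energy()` |
| Dynamics | position Verlet `r(t+Δt) = 2r(t) − r(t−Δt) + (F/m)Δt²`, Berendsen T/P coupling, RMSD/RMSF with Kabsch superposition | `run_md()`, `thermostat_update()`, `trajectory_rmsd()`, `trajectory_rmsf()` |
| Transition states | CI-NEB `Fᵢ = −∇E + κ(Rᵢ₊₁ − 2Rᵢ + Rᵢ₋₁)` (κ = 5 eV/Å², 10 images), finite-difference Hessian, one-imaginary-frequency validation `ω = √(λ_min/m_eff)`, descent-path (IRC-style) checks | `run_neb()`, `normal_modes()`, `classify_stationary_point()`, `descend_path()` |
| Free energy | umbrella sampling (MALA) + WHAM `W(R) = −k_BT ln P(R)` with bias removed; Eyring/TST rates | `run_umbrella_window()`, `wham_solve()`, `pmf_barrier()`, `tst_rate()` |
| H-bonds | geometric criterion: D···A ≤ 3.5 Å and ∠(D-H···A) ≥ 150° | `hbond_filter()`, `hbond_occupancy()` |
| Reporting | activation-energy reductions, error/IR tables, sensitivity and consistency checks over the QD-01…QD-15 reference series | `reduction_table()`, `error_analysis()`, `consistency_report()` |
| Synthetic data | seeded generators with truth records for all of the above | `gen_mn_cluster()`, `gen_double_well_surface()`, `gen_hbond_trajectory()`, `gen_substrate_series()` |

## Worked example

Find a reaction barrier three independent ways — closed form, CI-NEB, and
umbrella sampling + WHAM — then summarise the reference substrate series:

```r
library(enzymn)

dw <- gen_double_well_surface(surface_spec(barrier = 5))   # planted 5 kcal/mol
neb <- run_neb(-1, 1, dw$surface, neb_settings())
neb$barrier_forward
#> [1] 4.99571

wins <- lapply(seq_along(ws <- umbrella_ladder(-1.05, 1.05, 20, k = 200)),
               function(i) run_umbrella_window(dw$surface, ws[[i]],
                                               n_steps = 5e4, seed = 1000 + i))
pmf_barrier(wham_solve(wins, bin_width = 0.05), c(-1.3, -0.7), c(0.7, 1.3))
#> [1] 4.974661

nm <- normal_modes(finite_difference_hessian(dw$surface,
                                             neb$images[neb$saddle_index, ]))
nm$n_imaginary    # exactly one imaginary mode: a true transition state
#> [1] 1

red <- reduction_table(reference_table("activation_energies"))
c(mean = red$mean, max = red$max)
#>     mean      max
#> 36.92552 40.93960
red$max_substrate
#> [1] "QD-03"
```

The NEB and WHAM estimates bracket the planted 5 kcal/mol barrier to within
0.03 kcal/mol, the Hessian confirms a first-order saddle, and the reference
series shows a mean activation-energy reduction of 36.9% (maximum 40.9%,
substrate QD-03) for synergistic over enzyme-only catalysis.
`consistency_report()` lists which printed summary claims the tables
themselves support and which they do not.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the whole pipeline end to end from the installed package — the
reference-table statistics, the CI-NEB search with Hessian validation, the
20-window umbrella-sampling/WHAM free-energy profile with its TST rate, and
the coordination-shell and hydrogen-bond analyses — logging each stage's
numbers and writing the results object to `--out`. The `--seed` argument
drives every random draw, so runs are exactly reproducible.

## Documentation

The methods vignette (`vignettes/enzymn-methods.Rmd`) describes the models
and their assumptions, the unit system, every tunable parameter with its
default and rationale, what the synthetic worlds do and do not emulate, and
the package's numerical choices and known limitations.
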