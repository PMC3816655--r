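# diascore

Statistical estimation of protein–ligand binding free energy (ΔG) from the
direct protein–ligand interaction sampled by molecular dynamics, for
structural bioinformaticians and computational chemists who want an
MD-ensemble rescoring method that needs only a simulation of the complex —
no solvated-ligand reference simulation and no per-target training
compounds.

## The model

For each protein residue *i*, the ensemble mean van der Waals and
electrostatic interaction energies with the ligand, E<sup>vdW</sup>(i) and
E<sup>ele</sup>(i), and their fluctuations (population SD over frames)
S<sub>vdW</sub>(i) and S<sub>ele</sub>(i), are summed over residues and
combined linearly. The **direct interaction approximation without solvent
(DIAV)** is

ΔG = α Σ<sub>i</sub> E<sup>vdW</sup>(i) + α₂ Σ<sub>i</sub> S<sub>vdW</sub>(i) +
β Σ<sub>i</sub> E<sup>ele</sup>(i) + β₂ Σ<sub>i</sub> S<sub>ele</sub>(i) + τ S<sub>x</sub>

where S<sub>x</sub> is an entropy descriptor: the ensemble fluctuation of
the accessible surface area (x = ASA), of the rotatable dihedral angles
(x = DIH, circular statistics), or of the total vdW / electrostatic energy.
The **solvent-aware variant (DIAS)** replaces each Coulomb pair term by one
screened with a per-protein-atom effective dielectric constant
ε<sub>eff</sub> estimated from the ratio of solvated to vacuum
electrostatic forces, regularized by a parameter *x* so that
1 ≤ ε<sub>eff</sub> < ∞ even where the solvated force vanishes. The vdW
term supports generalized Lennard-Jones n–m forms (12-6, 9-6, 8-4, 6-3),
each with its minimum −ε at the equilibrium distance R<sub>e</sub>; the
soft LJ 8-4 form performs best on the packaged benchmark. All weights
(α, α₂, β, β₂, τ) are fitted by ordinary least squares against
experimental ΔG and assessed by leave-one-out cross-validation (LOO CV).

## Worked example

```r
library(diascore)

# published per-complex predictions for the 34-complex benchmark
b <- benchmark_table4()
dg_metrics(b$dg_dias, b$dg_exptl)
#> # A tibble: 1 × 2
#>     mae pearson_r
#>   <dbl>     <dbl>
#> 1  1.23     0.811

# a seeded toy complex: 110 atoms, jittered ensemble, fabricated forces
toy <- make_toy_complex(seed = 1, n_frames = 50)
dmap <- effective_dielectric(
  as.matrix(toy$forces[, c("Fx_real", "Fy_real", "Fz_real")]),
  as.matrix(toy$forces[, c("Fx_vac",  "Fy_vac",  "Fz_vac")]),
  x = 0.6, atom_id = toy$forces$atom_id)
extract_features(toy$frames, form = "8-4", dmap = dmap)[,
  c("sum_vdw", "sum_ele", "sum_ele_scaled", "S_ASA")]
#> # A tibble: 1 × 4
#>   sum_vdw sum_ele sum_ele_scaled S_ASA
#>     <dbl>   <dbl>          <dbl> <dbl>
#> 1   -4.24    49.6           21.3  40.5

# fit + leave-one-out on a synthetic benchmark-scale dataset
d  <- make_feature_dataset(seed = 1, noise_sd = 1)
cv <- loo_cv(d, model_kind = "diav", vdw_form = "8-4", property = "ASA")
cv
#> <dia_cv> leave-one-out over 34 complexes
#>   MAE = 0.950 kcal/mol, Pearson R = 0.889
#> <dia_params> diav model, LJ 8-4, S_ASA
#>   alpha=0.0370711 alpha2=0.0132246 beta=0.0071086 beta2=0.00307537 tau=-0.000358968
```

The benchmark call reproduces the headline accuracy of the solvent-aware
model: mean absolute error ≈ 1.2 kcal/mol and Pearson R ≈ 0.81 between
predicted and experimental ΔG over the 34 complexes. The toy/synthetic
calls show the full pipeline — feature extraction from an ensemble,
dielectric scaling, least-squares fitting and held-out error — at desk
scale. A command-line wrapper (`inst/scripts/dia`) exposes the same
operations as `simulate`, `extract`, `fit`, `loo`, `predict`,
`rank-poses` and `benchmark-table4` subcommands.

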