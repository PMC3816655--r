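---
title: "Direct-interaction estimation of protein–ligand binding free energy: models, descriptors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct-interaction estimation of protein-ligand binding free energy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diascore)
```

## The problem and the model family

Binding free energy (ΔG) rescoring methods that need per-target training
ligands (LIE with fitted weights, COMBINE with PLS-fitted per-residue
weights) cannot be applied to a target with a single known complex. The
direct-interaction approximation family estimates ΔG for *any* complex
from one MD simulation of that complex, using globally fitted weights.
Starting from a cumulant expansion of the free-energy perturbation
identity, the linear term yields an enthalpy-like sum of residue–ligand
interaction energies, and the second-order term motivates fluctuation
("entropy") descriptors.

The package implements four nested linear models over per-complex scalar
features:

* **simple** — ΔG = α·ΣᵢE^vdW(i) + β·ΣᵢE^ele(i). This is simultaneously
  solvent-free LIE and COMBINE with a residue-independent weight.
* **DIAV** — adds α₂·ΣᵢS_vdW(i) + β₂·ΣᵢS_ele(i) + τ·S_x, where S_vdW(i)
  and S_ele(i) are per-residue energy fluctuations over the ensemble and
  S_x is one entropy descriptor of the whole complex.
* **DIAS** — DIAV with each Coulomb pair term screened by a per-protein-atom
  effective dielectric constant before residue summation.
* **generalized** — DIAS/DIAV with additional τ_x·S_x terms, one per extra
  entropy property. On the published benchmark, combining two entropy
  terms did not improve accuracy, which is why the single-term DIAS is the
  recommended form.

All models are linear in (α, α₂, β, β₂, τ), so fitting is ordinary least
squares with no intercept; the DIAS regularizer *x* is the only nonlinear
parameter and is handled by an outer grid search.

### Where α₂ and β₂ act

The fluctuation weights multiply the *residue-summed* fluctuations
Σᵢ S_vdW(i) and Σᵢ S_ele(i). This choice keeps the model linear in all
five weights (a prerequisite for least-squares fitting), matches the
published parameter count, and is consistent with the small fitted
magnitudes (α₂ ≈ 0.01, β₂ ≈ −0.001 on the benchmark), which leave the
modulated energies close to the unmodulated ones.

## Energy terms

Van der Waals interactions use a generalized Lennard-Jones n–m form

E(r) = ε/(n−m) · [m·(R_e/r)ⁿ − n·(R_e/r)ᵐ],  (n,m) ∈ {(12,6), (9,6), (8,4), (6,3)}

normalized so that every variant has its minimum exactly −ε at r = R_e and
decays to zero at long range. The published typesetting of the softer
variants is not available, so this normalization — the unique one
consistent with "equilibrium distance" and "well depth" keeping their
AMBER meanings across all four forms — is a declared design choice. Pair
parameters follow the Lorentz–Berthelot/AMBER convention: R_e(ij) =
Rmin/2(i) + Rmin/2(j), ε(ij) = √(εᵢεⱼ). Softer exponent pairs penalize
atomic clashes less, which matters because the vdW term also absorbs
hydrophobic-contact signal; LJ 8-4 is the benchmark optimum and the
package default for fitting.

Electrostatics is Coulombic, 332.0637·q₁q₂/(ε_eff·r) kcal/mol with charges
in e and distances in Å. No interaction cutoff is applied by default: the
analysis operates on already-sampled ensembles, and truncation belongs to
the sampling engine, not the analysis. A cutoff remains available as an
option for sensitivity checks. Waters and monatomic ions are excluded at
the file boundary; only protein-residue–ligand terms enter the models.

## Ensemble descriptors

**Fluctuation** is everywhere the population standard deviation over
frames (zero for a single frame). The population rather than sample
estimator keeps descriptors in the property's own units, is exactly zero
on rigid ensembles, and avoids an arbitrary n−1 at the tiny ensemble sizes
used in testing; at the production scale of hundreds of frames the
difference is negligible.

* **S_ASA** — SD over frames of the total solvent-accessible surface area
  (Å²). A solvation-weighted mode (Σ solv_param·ASA_atom, kcal/mol) is
  available but off by default, since it is not established whether the
  atomic solvation parameters should weight the fluctuation.
* **S_DIH** — sum over rotatable dihedrals (ligand and protein; both are
  included by default and the set is configurable, as the published
  definition covers "the complex system" without restriction) of the
  circular SD √(−2·ln R̄) of the torsion angle, in radians. Circular
  statistics make a torsion wobbling between +179° and −179° a ~1°
  fluctuation rather than ~179°.
* **S_VDW / S_ELE** — SD over frames of the total protein–ligand vdW /
  electrostatic energy (kcal/mol).

ASA uses the Shrake–Rupley sphere-point method with a deterministic
Fibonacci lattice, probe radius 1.4 Å (water) and 960 points per atom by
default — at 960 points an isolated sphere is reproduced within 1%, and
the deterministic lattice keeps ensembles bit-reproducible. The
implementation is validated against the analytic isolated-sphere area and
an independent latitude-band grid integration for intersecting spheres.

## Effective dielectric constants

The screening a protein atom's electrostatics experiences is estimated
from paired force sets: the electrostatic force on the atom computed in
explicit solvent (F_real) and in vacuum (F_vac). Two raw estimators are
provided: the magnitude ratio |F_vac|/|F_real| (mode 19, the default, which
performed better on the published benchmark) and the projection of F_vac
on the F_real direction divided by |F_real| (mode 18). Because the raw
ratio diverges where the solvated force nearly vanishes, it is regularized
as

ε_eff = max(1, (|F_vac| + x·F̄) / (|F_real| + x·F̄)),  F̄ = mean |F_vac|,

which is finite for any x > 0, reduces to the raw ratio in the strong-force
limit, and respects the bound ε_eff ≥ 1 (screening weaker than vacuum is
absorbed by the fitted β). The exact published algebra of the estimator
and its regularizer is not available in the source text; these forms are
declared reconstructions chosen to satisfy the documented properties
(boundedness near zero denominators, the 1 < ε_eff bound, and the
strong-force limit). The benchmark optimum x = 0.6 is the default, and the
grid 0.1–2.0 in steps of 0.1 covers it during fitting. ε_eff is assigned
per protein atom and applied to each Coulomb pair term before residue
summation — the finest application consistent with aggregating over ligand
atoms. Force sets are *inputs* (TSV files): producing them requires
explicit-solvent MD, which is out of scope; the fixture generator
fabricates consistent pairs with known screening factors instead.

## Fitting and validation

Least squares is solved by QR decomposition; rank deficiency raises an
error naming the collinear columns rather than silently dropping terms.
Leave-one-out cross-validation refits all linear weights for each held-out
complex; the DIAS x is fitted once on the full data and held fixed across
folds (matching the single published x; per-fold refitting is available
via `refit_x`). The reported parameter set is the full-data fit — whether
published parameter columns are full-data or per-fold averages is not
stated in the source, and the full-data fit is the reproducible choice.
"Average error" is mean absolute error; this reading reproduces the
published per-complex benchmark columns' summary (MAE 1.227 ≈ printed
1.22, R 0.811 ≈ printed 0.81 for the solvent-aware column). The printed
summary rows of the weaker columns differ from recomputation by ≤ 0.05
kcal/mol, consistent with rounding of the two-decimal per-complex entries.

Pose ranking sorts candidate poses of one complex by predicted ΔG with
stable input-order tie-breaking, and success rates count best-pose
RMSD < threshold. The published docking success percentages depend on the
original docking poses and MD structures and are therefore not
reproducible here; the protocol (ranking + counting) is what the package
implements and tests.

## The synthetic generators: what they emulate and what they do not

`make_toy_complex()` builds residues on a spherical shell around a central
helical ligand (a loose pocket with all frame-0 pair distances > 1.5 Å),
draws AMBER-like per-atom parameters, and emulates thermal motion as
i.i.d. Gaussian positional jitter (default SD 0.3 Å per coordinate,
roughly the heavy-atom RMSF scale of a stable binding site at 310 K;
default 200 frames at 110 atoms stands in for the published 1000-frame
production ensembles at desk scale). Fabricated force pairs use per-atom
screening factors drawn uniformly in [1, 10], bracketing the protein
interior (~2–4) and approaching bulk-water screening, and satisfy
F_vac = s·F_real exactly so the dielectric estimator has a known truth.
What the jitter ensemble does **not** emulate: correlated motions,
anharmonic side-chain transitions, solvent structure, or realistic
energy–geometry coupling. Passing tests on these fixtures therefore
demonstrate correctness of the *estimators and pipeline*, not predictive
accuracy on real MD data.

`make_feature_dataset()` draws feature vectors from ranges chosen so that
benchmark-scale weights give predicted ΔG spanning roughly −14 to −4
kcal/mol (the benchmark range), and adds Gaussian noise to the response
(default SD 1.0 kcal/mol, the method's benchmark error scale). With zero
noise, least squares recovers the generating weights to machine precision,
which anchors the parameter-recovery tests; published benchmark
*parameters* are not recoverable at desk scale because they require the
original 2-ns MD feature values.

## Numerical choices and degenerate inputs

* Population SD throughout; circular SD clamps R̄ ≤ 1 before the log, so a
  numerically rigid torsion gives ~10⁻⁸ rad rather than NaN.
* Coincident atoms: ASA warns (`diascore_degenerate_geometry`) and
  continues; coincident protein/ligand atoms in an energy evaluation are a
  hard error (zero separation).
* ε_eff at |F_real| = 0 is finite for x > 0 and reported as the raw ratio
  ∞ only in the unregularized `eps_raw` column.
* All errors are classed conditions (`diascore_*_error`), so callers can
  branch on failure modes.
* Test and example problem sizes (110-atom toys, 200-frame ensembles,
  960 sphere points, 34-row synthetic datasets, 20-seed repeats) were
  chosen to exercise every code path at interactive timescales while
  matching the benchmark's statistical scale where it matters.

## Known limitations

* The softer-LJ prefactors, the dielectric estimator algebra and the
  placement of α₂/β₂ are reconstructions constrained by documented
  properties, not transcriptions of the original typeset equations; anyone
  holding the original equations should check these three points first.
* Force-set generation (explicit-solvent MD) and docking-pose generation
  are out of scope; the package consumes their outputs.
* Metalloprotein complexes are outside the model's validity (covalent
  metal–ligand bonds are not representable by the force field the features
  assume).
* The pure-R Shrake–Rupley implementation is adequate for hundreds of
  atoms per frame; very large systems would want a compiled neighbor-list
  implementation.
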