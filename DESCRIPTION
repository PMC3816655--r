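Package: diascore
Title: Direct Interaction Approximation Scoring of Protein-Ligand Binding Free Energy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical estimation of protein-ligand binding free energy from
    ensemble-averaged per-residue interaction energies. Implements the direct
    interaction approximation without solvent (DIAV) and with solvent (DIAS):
    per-residue van der Waals (generalized Lennard-Jones n-m forms) and Coulomb
    energy decomposition over molecular-dynamics ensembles, fluctuation-based
    entropy descriptors (accessible surface area, dihedral angles, interaction
    energies), effective dielectric scaling from solvated/vacuum force ratios,
    least-squares parameter fitting with leave-one-out cross-validation, and
    binding-pose ranking. Ships a 34-complex benchmark table and deterministic
    synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    jsonlite,
    ggplot2,
    generics,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
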