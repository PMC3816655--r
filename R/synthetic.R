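# Deterministic toy generators. These are statistical stand-ins for real
# MD ensembles: Gaussian positional jitter around a packed reference
# geometry, and fabricated solvated/vacuum force pairs with known per-atom
# screening factors. They make every downstream operation testable at desk
# scale; they do not emulate MD physics.

#' Generate a toy protein-ligand complex with ensemble and force sets
#'
#' Builds a deterministic toy system: protein residues arranged on a
#' spherical shell around a central ligand (a loose binding pocket),
#' per-atom parameters drawn from AMBER-like ranges, an ensemble of frames
#' obtained by adding Gaussian positional jitter to the reference
#' conformation, and a fabricated pair of per-protein-atom force sets with
#' known screening factors `s` in `[1, 10]` such that
#' `F_vac = s * F_real` (so the dielectric estimator can be validated
#' exactly).
#'
#' @param seed Integer seed; equal seeds give bit-identical output.
#' @param n_residues Protein residues.
#' @param atoms_per_residue Atoms per residue.
#' @param n_ligand_atoms Ligand atoms.
#' @param n_frames Ensemble frames.
#' @param jitter Positional jitter SD per coordinate, Angstrom (0 = rigid).
#' @param charge_scale SD of atomic partial charges, elementary units.
#' @return List with elements `system` ([complex_system()]), `frames`
#'   ([ensemble_frames()]), `forces` (tibble: `atom_id`, `s_true`,
#'   `Fx_real`..`Fz_real`, `Fx_vac`..`Fz_vac`).
#' @examples
#' toy <- make_toy_complex(seed = 1, n_frames = 3)
#' toy$system
#' @export
make_toy_complex <- function(seed = 1, n_residues = 20, atoms_per_residue = 5,
                             n_ligand_atoms = 10, n_frames = 200,
                             jitter = 0.3, charge_scale = 0.2) {
  stopifnot(n_residues >= 1, atoms_per_residue >= 1, n_ligand_atoms >= 1,
            n_frames >= 1, jitter >= 0)
  withr::with_seed(seed, {
    # ligand: short helix at the origin, 1.8 A rise -> no internal clash
    t <- seq_len(n_ligand_atoms)
    lig <- cbind(1.2 * cos(t * 2), 1.2 * sin(t * 2),
                 1.1 * (t - mean(t)))
    # residue centres on a shell well outside the ligand
    shell_r <- max(8, 1.1 * max(sqrt(rowSums(lig^2))) + 5)
    centres <- fibonacci_sphere(n_residues) * shell_r
    offs <- fibonacci_sphere(max(atoms_per_residue, 4)) * 1.3
    prot <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
      sweep(offs[seq_len(atoms_per_residue), , drop = FALSE], 2,
            centres[i, ], `+`)
    }))
    coords <- rbind(prot, lig)
    n_prot <- nrow(prot)
    n_atoms <- nrow(coords)
    if (min(stats::dist(coords)) < 1.5) {
      abort("Toy packing failed: atoms closer than 1.5 A in frame 0.",
            class = "diascore_generation_error")
    }
    atoms <- tibble(
      atom_id = seq_len(n_atoms),
      residue_index = c(rep(seq_len(n_residues), each = atoms_per_residue),
                        rep(n_residues + 1L, n_ligand_atoms)),
      is_ligand = c(rep(FALSE, n_prot), rep(TRUE, n_ligand_atoms)),
      charge = rnorm(n_atoms, sd = charge_scale),
      lj_re = runif(n_atoms, 1.5, 2.0),
      lj_eps = runif(n_atoms, 0.05, 0.2),
      solv_param = runif(n_atoms, 0.005, 0.03),
      radius = runif(n_atoms, 1.2, 1.8)
    )
    # rotatable dihedrals: consecutive ligand quadruples + a protein one
    dih <- list()
    if (n_ligand_atoms >= 4) {
      dih <- lapply(seq_len(n_ligand_atoms - 3), function(k)
        n_prot + k + 0:3)
    }
    if (atoms_per_residue >= 4) {
      dih <- c(dih, list(1:4))
    }
    sys <- complex_system(atoms, coords, dih)
    frames <- lapply(seq_len(n_frames), function(k)
      coords + matrix(rnorm(3 * n_atoms, sd = jitter), n_atoms, 3))
    s <- runif(n_prot, 1, 10)
    F_real <- matrix(rnorm(3 * n_prot, sd = 5), n_prot, 3)
    F_vac <- F_real * s
    forces <- tibble(
      atom_id = seq_len(n_prot), s_true = s,
      Fx_real = F_real[, 1], Fy_real = F_real[, 2], Fz_real = F_real[, 3],
      Fx_vac = F_vac[, 1], Fy_vac = F_vac[, 2], Fz_vac = F_vac[, 3]
    )
    list(system = sys,
         frames = ensemble_frames(sys, frames),
         forces = forces)
  })
}

#' Generate a synthetic feature dataset with known true parameters
#'
#' Draws complex feature records from ranges mimicking the benchmark scale
#' (predicted binding free energies spanning roughly -14 to -4 kcal/mol
#' under benchmark-scale parameters) and sets
#' `dg_exptl = predict_dg(features, true_params) + N(0, noise_sd)`. With
#' `noise_sd = 0` the generating parameters are exactly recoverable by
#' least squares, which anchors the parameter-recovery tests.
#'
#' @param seed Integer seed.
#' @param true_params [dia_params()] generating the response.
#' @param n Number of complexes.
#' @param noise_sd Gaussian noise SD on `dg_exptl`, kcal/mol.
#' @return Feature tibble compatible with [fit_params()] / [loo_cv()].
#' @export
make_feature_dataset <- function(seed = 1, true_params = NULL, n = 34,
                                 noise_sd = 1.0) {
  true_params <- true_params %||% dia_params(
    alpha = 0.0378, alpha2 = 0.0093, beta = 0.0082, beta2 = -0.0011,
    tau = -2.4178e-4, vdw_form = "8-4", property = "ASA",
    model_kind = "diav")
  withr::with_seed(seed, {
    d <- tibble(
      complex_id = sprintf("syn%03d", seq_len(n)),
      sum_vdw = runif(n, -280, -60),
      sum_ele = runif(n, -450, -40),
      sum_fluct_vdw = runif(n, 20, 90),
      sum_fluct_ele = runif(n, 30, 140),
      S_ASA = runif(n, 1500, 12000),
      S_DIH = runif(n, 2, 40),
      S_VDW = runif(n, 1, 12),
      S_ELE = runif(n, 2, 25),
      n_frames = NA_integer_,
      vdw_form = true_params$vdw_form
    )
    d$sum_ele_scaled <- d$sum_ele / runif(n, 1.2, 3.0)
    d$dg_exptl <- predict_dg(d, true_params) + rnorm(n, sd = noise_sd)
    d
  })
}
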