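#' Generalized Lennard-Jones n-m functional forms
#'
#' The van der Waals interaction is modelled by one of four Lennard-Jones
#' variants, written in the generalized n-m form
#' \deqn{E(r) = \frac{\epsilon}{n-m}\left[m\left(\frac{R_e}{r}\right)^n -
#'   n\left(\frac{R_e}{r}\right)^m\right]}
#' with exponent pairs (12,6), (9,6), (8,4) and (6,3). The normalization is
#' chosen so that every form has its minimum exactly at the equilibrium
#' distance \eqn{R_e} with depth \eqn{-\epsilon}, and decays to zero at large
#' separation. Softer exponent pairs (8-4, 6-3) penalize atomic clashes less
#' and let the term absorb part of the hydrophobic-contact signal.
#'
#' @name vdw_forms
#' @return `vdw_forms()` returns the character vector of supported form tags.
#' @examples
#' vdw_forms()
#' @export
vdw_forms <- function() c("12-6", "9-6", "8-4", "6-3")

# exponent pair for a form tag
vdw_exponents <- function(form) {
  form <- match.arg(form, vdw_forms())
  switch(form,
    "12-6" = c(12, 6),
    "9-6"  = c(9, 6),
    "8-4"  = c(8, 4),
    "6-3"  = c(6, 3)
  )
}

#' Lennard-Jones pair energy
#'
#' @param r Interatomic distance in Angstrom (vectorized).
#' @param Re Pair equilibrium distance in Angstrom.
#' @param eps Pair well depth in kcal/mol (>= 0).
#' @param form One of [vdw_forms()]; default `"12-6"`.
#' @return Energy in kcal/mol; `-eps` at `r = Re`, tending to 0 as `r` grows.
#' @examples
#' lj_energy(3.8, Re = 3.8, eps = 0.1)          # exactly -0.1
#' lj_energy(3.0, Re = 3.8, eps = 0.1, "8-4")   # repulsive side, softer form
#' @export
lj_energy <- function(r, Re, eps, form = "12-6") {
  nm <- vdw_exponents(form)
  if (any(!is.finite(r)) || any(r <= 0)) {
    abort("`r` must be finite and > 0.", class = "diascore_domain_error")
  }
  if (any(!is.finite(Re)) || any(Re <= 0) || any(!is.finite(eps)) || any(eps < 0)) {
    abort("`Re` must be > 0 and `eps` >= 0, both finite.",
          class = "diascore_invalid_parameter")
  }
  n <- nm[1]; m <- nm[2]
  q <- Re / r
  eps / (n - m) * (m * q^n - n * q^m)
}

#' Coulomb pair energy
#'
#' Electrostatic interaction energy between two point charges,
#' `332.0637 * q1 * q2 / (eps_scale * r)` kcal/mol, with the conversion
#' constant for charges in elementary units and distance in Angstrom.
#' `eps_scale` is the (effective) dielectric constant dividing the pair term.
#'
#' @param q1,q2 Partial charges in elementary-charge units (vectorized).
#' @param r Distance in Angstrom.
#' @param eps_scale Dimensionless dielectric scale, >= 1 (1 = vacuum).
#' @return Energy in kcal/mol.
#' @examples
#' coulomb_pair_energy(1, 1, 1)          # the bare constant, 332.0637
#' coulomb_pair_energy(1, -1, 3, 2)      # screened salt-bridge-like pair
#' @export
coulomb_pair_energy <- function(q1, q2, r, eps_scale = 1) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    abort("`r` must be finite and > 0.", class = "diascore_domain_error")
  }
  if (any(!is.finite(eps_scale)) || any(eps_scale <= 0)) {
    abort("`eps_scale` must be finite and positive.",
          class = "diascore_invalid_parameter")
  }
  COULOMB_K * q1 * q2 / (eps_scale * r)
}

#' Combine per-atom Lennard-Jones parameters into pair parameters
#'
#' Lorentz-Berthelot combination in the AMBER convention: per-atom `lj_re`
#' holds the Rmin/2 component, so the pair equilibrium distance is the sum,
#' and the pair well depth is the geometric mean of the atomic well depths.
#'
#' @param re1,eps1 Rmin/2 (Angstrom) and well depth (kcal/mol) of atom 1.
#' @param re2,eps2 Same for atom 2 (all vectorized).
#' @return A list with numeric elements `Re` and `eps`.
#' @examples
#' combine_pair_params(1.9, 0.1, 1.9, 0.1)   # Re = 3.8, eps = 0.1
#' @export
combine_pair_params <- function(re1, eps1, re2, eps2) {
  if (any(!is.finite(c(re1, re2, eps1, eps2))) ||
      any(re1 <= 0) || any(re2 <= 0) || any(eps1 < 0) || any(eps2 < 0)) {
    abort("LJ parameters must be finite with lj_re > 0 and lj_eps >= 0.",
          class = "diascore_invalid_parameter")
  }
  list(Re = re1 + re2, eps = sqrt(eps1 * eps2))
}

# ---- complex system container -------------------------------------------

#' Build a protein-ligand complex system
#'
#' Bundles the per-atom parameter table, a reference conformation, and the
#' ligand selection into the container the energy and descriptor functions
#' consume. Atoms are 1-indexed; protein residue indices must be contiguous
#' from 1; ligand atoms carry `is_ligand = TRUE` and their `residue_index`
#' is ignored by the per-residue decomposition.
#'
#' @param atoms Tibble with columns `atom_id`, `residue_index`, `is_ligand`,
#'   `charge` (e), `lj_re` (Rmin/2, Angstrom), `lj_eps` (kcal/mol),
#'   `solv_param` (kcal/mol/A^2), `radius` (Angstrom).
#' @param coords Numeric matrix `n_atoms x 3`, Angstrom.
#' @param rotatable_dihedrals Optional list of length-4 integer vectors of
#'   atom ids defining rotatable torsions (ligand and/or protein side chains).
#' @return An object of class `complex_system`.
#' @export
complex_system <- function(atoms, coords, rotatable_dihedrals = list()) {
  atoms <- as_tibble(atoms)
  required <- c("atom_id", "residue_index", "is_ligand", "charge",
                "lj_re", "lj_eps", "solv_param", "radius")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    abort(paste0("`atoms` is missing columns: ", paste(missing, collapse = ", ")),
          class = "diascore_invalid_parameter")
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3) {
    abort("`coords` must be an n_atoms x 3 matrix.", class = "diascore_shape_error")
  }
  if (!any(atoms$is_ligand)) {
    abort("The system has no ligand atoms.", class = "diascore_selection_error")
  }
  if (any(atoms$lj_re <= 0) || any(atoms$radius <= 0) || any(atoms$lj_eps < 0)) {
    abort("Atom parameters violate lj_re > 0, radius > 0, lj_eps >= 0.",
          class = "diascore_invalid_parameter")
  }
  prot_res <- sort(unique(as.integer(atoms$residue_index[!atoms$is_ligand])))
  if (length(prot_res) && !identical(prot_res, seq_along(prot_res))) {
    abort("Protein residue indices must be contiguous from 1.",
          class = "diascore_invalid_parameter")
  }
  bad <- unlist(rotatable_dihedrals)
  if (length(bad) && (any(bad < 1) || any(bad > nrow(atoms)))) {
    abort("Dihedral atom ids reference atoms outside the system.",
          class = "diascore_invalid_parameter")
  }
  structure(
    list(
      atoms = atoms,
      coords = coords,
      rotatable_dihedrals = rotatable_dihedrals,
      residue_count = length(prot_res),
      ligand_atom_ids = atoms$atom_id[atoms$is_ligand]
    ),
    class = "complex_system"
  )
}

#' @export
print.complex_system <- function(x, ...) {
  cat("<complex_system> ", nrow(x$atoms), " atoms, ",
      x$residue_count, " protein residues, ",
      length(x$ligand_atom_ids), " ligand atoms, ",
      length(x$rotatable_dihedrals), " rotatable dihedrals\n", sep = "")
  invisible(x)
}

# pairwise energy matrices between protein and ligand atoms for one
# conformation; eps_atom optionally screens each protein atom's Coulomb terms
pair_energy_matrices <- function(system, coords, form, eps_atom = NULL,
                                 cutoff = NULL) {
  at <- system$atoms
  ip <- which(!at$is_ligand)
  il <- which(at$is_ligand)
  P <- coords[ip, , drop = FALSE]
  L <- coords[il, , drop = FALSE]
  # squared distance matrix |p - l|^2
  d2 <- outer(rowSums(P^2), rowSums(L^2), `+`) - 2 * P %*% t(L)
  d <- sqrt(pmax(d2, 0))
  if (any(d <= 0)) {
    abort("Coincident protein and ligand atoms give zero separation.",
          class = "diascore_domain_error")
  }
  Re <- outer(at$lj_re[ip], at$lj_re[il], `+`)
  eps <- sqrt(outer(at$lj_eps[ip], at$lj_eps[il]))
  nm <- vdw_exponents(form)
  q <- Re / d
  Evdw <- eps / (nm[1] - nm[2]) * (nm[2] * q^nm[1] - nm[1] * q^nm[2])
  Eele <- COULOMB_K * outer(at$charge[ip], at$charge[il]) / d
  if (!is.null(eps_atom)) Eele <- Eele / eps_atom[ip]
  if (!is.null(cutoff)) {
    keep <- d <= cutoff
    Evdw <- Evdw * keep
    Eele <- Eele * keep
  }
  list(vdw = Evdw, ele = Eele, protein_idx = ip, ligand_idx = il)
}

#' Per-residue protein-ligand interaction energies for one conformation
#'
#' Sums Lennard-Jones and Coulomb pair energies over all
#' (protein-atom-in-residue, ligand-atom) pairs, giving the per-residue
#' decomposition the binding free-energy models are built on. No distance
#' cutoff is applied by default.
#'
#' @param system A [complex_system()].
#' @param coords Conformation matrix `n_atoms x 3` (default: the system's
#'   reference coordinates).
#' @param form Lennard-Jones form tag, see [vdw_forms()].
#' @param eps_atom Optional per-atom dielectric vector (length n_atoms; only
#'   protein entries are used) dividing each Coulomb pair term.
#' @param cutoff Optional pair-distance cutoff in Angstrom.
#' @return Tibble with one row per protein residue: `residue_index`,
#'   `e_vdw`, `e_ele` (kcal/mol).
#' @export
residue_ligand_energies <- function(system, coords = system$coords,
                                    form = "12-6", eps_atom = NULL,
                                    cutoff = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(system$atoms)) {
    abort("Conformation does not match the system atom count.",
          class = "diascore_shape_error")
  }
  pm <- pair_energy_matrices(system, coords, form, eps_atom, cutoff)
  res <- system$atoms$residue_index[pm$protein_idx]
  tibble(
    residue_index = seq_len(system$residue_count),
    e_vdw = as.numeric(rowsum(rowSums(pm$vdw), res)[, 1]),
    e_ele = as.numeric(rowsum(rowSums(pm$ele), res)[, 1])
  )
}
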