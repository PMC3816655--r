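#' Bundle an ordered conformational ensemble
#'
#' @param system A [complex_system()].
#' @param frames List of `n_atoms x 3` coordinate matrices (Angstrom), in
#'   trajectory order.
#' @param frame_interval Sampling interval between frames, ps.
#' @return An object of class `ensemble_frames`.
#' @export
ensemble_frames <- function(system, frames, frame_interval = 1) {
  if (length(frames) < 1) {
    abort("An ensemble needs at least one frame.", class = "diascore_empty_ensemble")
  }
  frames <- lapply(frames, as.matrix)
  nat <- nrow(system$atoms)
  bad <- which(vapply(frames, nrow, 0L) != nat)
  if (length(bad)) {
    abort(paste0("Frame ", bad[1], " has the wrong atom count."),
          class = "diascore_shape_error")
  }
  structure(list(system = system, frames = frames,
                 frame_interval = frame_interval),
            class = "ensemble_frames")
}

#' @export
print.ensemble_frames <- function(x, ...) {
  cat("<ensemble_frames> ", length(x$frames), " frames x ",
      nrow(x$system$atoms), " atoms (", x$frame_interval, " ps interval)\n",
      sep = "")
  invisible(x)
}

# population standard deviation (fluctuation); 0 for a single observation
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Ensemble mean and fluctuation of per-residue interaction energies
#'
#' For each protein residue, the mean over frames of the residue-ligand van
#' der Waals and electrostatic energies, and their fluctuations (population
#' standard deviation over frames). These are the E(i) and S(i) terms of the
#' direct-interaction binding models. If `dmap` is supplied, a
#' dielectric-scaled electrostatic mean (`mean_ele_scaled`) is computed
#' alongside, with each protein atom's Coulomb terms divided by its
#' effective dielectric constant before residue summation.
#'
#' @param frames An [ensemble_frames()] object.
#' @param form Lennard-Jones form tag.
#' @param dmap Optional dielectric map tibble from [effective_dielectric()].
#' @param cutoff Optional pair-distance cutoff in Angstrom.
#' @return Tibble with columns `residue_index`, `mean_vdw`, `mean_ele`,
#'   `fluct_vdw`, `fluct_ele` and, when `dmap` is given, `mean_ele_scaled`
#'   (all kcal/mol).
#' @export
ensemble_interaction_profile <- function(frames, form = "12-6", dmap = NULL,
                                         cutoff = NULL) {
  sys <- frames$system
  eps_atom <- dielectric_vector(sys, dmap)
  nf <- length(frames$frames)
  nres <- sys$residue_count
  vdw <- matrix(0, nf, nres)
  ele <- matrix(0, nf, nres)
  eles <- if (!is.null(eps_atom)) matrix(0, nf, nres)
  for (k in seq_len(nf)) {
    e <- residue_ligand_energies(sys, frames$frames[[k]], form, cutoff = cutoff)
    vdw[k, ] <- e$e_vdw
    ele[k, ] <- e$e_ele
    if (!is.null(eps_atom)) {
      es <- residue_ligand_energies(sys, frames$frames[[k]], form,
                                    eps_atom = eps_atom, cutoff = cutoff)
      eles[k, ] <- es$e_ele
    }
  }
  out <- tibble(
    residue_index = seq_len(nres),
    mean_vdw = colMeans(vdw),
    mean_ele = colMeans(ele),
    fluct_vdw = apply(vdw, 2, pop_sd),
    fluct_ele = apply(ele, 2, pop_sd)
  )
  if (!is.null(eps_atom)) out$mean_ele_scaled <- colMeans(eles)
  out
}

#' Dielectric-scaled electrostatic profile
#'
#' Convenience wrapper around [ensemble_interaction_profile()] that requires
#' a dielectric map, yielding the solvent-aware (DIAS) electrostatics. A map
#' with all effective dielectric constants equal to 1 reproduces the
#' unscaled profile exactly.
#'
#' @inheritParams ensemble_interaction_profile
#' @param dmap Dielectric map tibble from [effective_dielectric()]; must
#'   cover every protein atom.
#' @return As [ensemble_interaction_profile()], with `mean_ele_scaled`.
#' @export
scaled_ele_profile <- function(frames, dmap, form = "12-6", cutoff = NULL) {
  if (is.null(dmap)) {
    abort("`dmap` is required for the scaled profile.",
          class = "diascore_coverage_error")
  }
  ensemble_interaction_profile(frames, form, dmap = dmap, cutoff = cutoff)
}

# expand a dielectric map tibble (atom_id, eps_eff) to a per-atom vector
dielectric_vector <- function(system, dmap) {
  if (is.null(dmap)) return(NULL)
  prot_ids <- system$atoms$atom_id[!system$atoms$is_ligand]
  miss <- setdiff(prot_ids, dmap$atom_id)
  if (length(miss)) {
    abort(paste0("Dielectric map is missing protein atoms: ",
                 paste(head(miss, 5), collapse = ", ")),
          class = "diascore_coverage_error")
  }
  v <- rep(1, nrow(system$atoms))
  v[match(dmap$atom_id, system$atoms$atom_id)] <- dmap$eps_eff
  v
}

# ---- dihedral geometry ---------------------------------------------------

# torsion angle (radians, in (-pi, pi]) for rows of four atom positions
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# circular (directional) SD in radians: sqrt(-2 log Rbar)
circular_sd <- function(theta) {
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  rbar <- min(rbar, 1)
  sqrt(-2 * log(rbar))
}

#' Ensemble entropy descriptor S_x
#'
#' The fluctuation over an ensemble of a property related to the
#' configurational entropy of the complex:
#' \describe{
#'   \item{`ASA`}{population SD over frames of the total accessible surface
#'     area (Angstrom^2; kcal/mol in solvation-weighted mode).}
#'   \item{`DIH`}{sum over rotatable dihedrals of the circular standard
#'     deviation of the torsion angle (radians); circular statistics handle
#'     the +/-180 degree wraparound.}
#'   \item{`VDW`, `ELE`}{population SD over frames of the total
#'     protein-ligand van der Waals / electrostatic energy (kcal/mol).}
#' }
#' Rigid ensembles give 0 for every property.
#'
#' @param frames An [ensemble_frames()] object.
#' @param property One of `"ASA"`, `"DIH"`, `"VDW"`, `"ELE"`.
#' @param form Lennard-Jones form for the `VDW` property.
#' @param probe,n_points,weighted ASA settings, see [asa_property()].
#' @return Tibble with columns `property` and `value` (one row).
#' @export
entropy_descriptor <- function(frames, property = c("ASA", "DIH", "VDW", "ELE"),
                               form = "12-6", probe = 1.4, n_points = 960,
                               weighted = FALSE) {
  property <- match.arg(property)
  sys <- frames$system
  value <- switch(property,
    ASA = pop_sd(vapply(frames$frames, function(x)
      asa_property(sys, x, probe, n_points, weighted), 0)),
    DIH = {
      dl <- sys$rotatable_dihedrals
      if (!length(dl)) {
        abort("DIH descriptor requires rotatable dihedrals in the system.",
              class = "diascore_configuration_error")
      }
      sum(vapply(dl, function(idx) {
        th <- vapply(frames$frames, function(x)
          dihedral_angle(x[idx[1], ], x[idx[2], ], x[idx[3], ], x[idx[4], ]), 0)
        circular_sd(th)
      }, 0))
    },
    VDW = pop_sd(vapply(frames$frames, function(x)
      sum(residue_ligand_energies(sys, x, form)$e_vdw), 0)),
    ELE = pop_sd(vapply(frames$frames, function(x)
      sum(residue_ligand_energies(sys, x, form)$e_ele), 0))
  )
  tibble(property = property, value = value)
}

#' Extract the scalar feature set of one complex
#'
#' Runs the full descriptor pipeline on an ensemble and returns the one-row
#' feature record the binding free-energy models consume: residue-summed
#' mean energies, residue-summed fluctuations, and the entropy descriptors.
#'
#' @param frames An [ensemble_frames()] object.
#' @param form Lennard-Jones form tag.
#' @param dmap Optional dielectric map for the solvent-scaled
#'   electrostatics (`sum_ele_scaled` is `NA` without it).
#' @param complex_id Identifier carried into the output.
#' @param dg_exptl Optional experimental binding free energy, kcal/mol.
#' @param probe,n_points,weighted ASA settings.
#' @param cutoff Optional pair-distance cutoff, Angstrom.
#' @param properties Entropy descriptors to compute; `"DIH"` is skipped
#'   automatically when the system declares no rotatable dihedrals.
#' @return One-row tibble with columns `complex_id`, `sum_vdw`, `sum_ele`,
#'   `sum_ele_scaled`, `sum_fluct_vdw`, `sum_fluct_ele`, `S_ASA`, `S_DIH`,
#'   `S_VDW`, `S_ELE`, `n_frames`, `vdw_form`, `dg_exptl`.
#' @export
extract_features <- function(frames, form = "12-6", dmap = NULL,
                             complex_id = "complex", dg_exptl = NA_real_,
                             probe = 1.4, n_points = 960, weighted = FALSE,
                             cutoff = NULL,
                             properties = c("ASA", "DIH", "VDW", "ELE")) {
  prof <- ensemble_interaction_profile(frames, form, dmap = dmap,
                                       cutoff = cutoff)
  if (!length(frames$system$rotatable_dihedrals)) {
    properties <- setdiff(properties, "DIH")
  }
  s <- setNames(rep(NA_real_, 4), c("ASA", "DIH", "VDW", "ELE"))
  for (p in properties) {
    s[[p]] <- entropy_descriptor(frames, p, form, probe, n_points, weighted)$value
  }
  tibble(
    complex_id = complex_id,
    sum_vdw = sum(prof$mean_vdw),
    sum_ele = sum(prof$mean_ele),
    sum_ele_scaled = if ("mean_ele_scaled" %in% names(prof))
      sum(prof$mean_ele_scaled) else NA_real_,
    sum_fluct_vdw = sum(prof$fluct_vdw),
    sum_fluct_ele = sum(prof$fluct_ele),
    S_ASA = s[["ASA"]], S_DIH = s[["DIH"]],
    S_VDW = s[["VDW"]], S_ELE = s[["ELE"]],
    n_frames = length(frames$frames),
    vdw_form = form,
    dg_exptl = dg_exptl
  )
}
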