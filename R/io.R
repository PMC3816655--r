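# File-format boundary. PDB coordinates are Angstrom; atom numbering is
# 1-based both in files and internally. Waters and monatomic ions are
# dropped on input: the models use protein-residue/ligand terms only.

WATER_RESNAMES <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD")
ION_RESNAMES <- c("NA", "CL", "K", "MG", "CA", "ZN", "FE", "MN", "BR", "IOD",
                  "NA+", "CL-", "SOD", "CLA")

#' Read a per-atom parameter table
#'
#' TSV with columns `atom_name`, `residue_name`, `charge_e`, `rmin_half_A`,
#' `eps_kcal`, `solv_param`, `radius_A`: partial charge (e), Lennard-Jones
#' Rmin/2 (Angstrom) and well depth (kcal/mol), atomic solvation parameter
#' (kcal/mol/A^2) and ASA radius (Angstrom), keyed by residue and atom
#' name. A reduced AMBER-like default set covering the packaged fixtures
#' ships with the package.
#'
#' @param path TSV path; default the packaged table.
#' @return Tibble of parameter rows.
#' @export
read_param_table <- function(path = system.file("extdata", "toy_params.tsv",
                                                package = "diascore",
                                                mustWork = TRUE)) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("atom_name", "residue_name", "charge_e", "rmin_half_A",
            "eps_kcal", "solv_param", "radius_A")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    abort(paste0("Parameter table is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "diascore_parameter_error")
  }
  d
}

#' Read a protein-ligand complex structure from a PDB file
#'
#' Parses the structure, drops waters and monatomic ions, identifies the
#' ligand (explicit residue name, or by default the largest HETATM residue
#' that is not water/ion), assigns contiguous protein residue indices in
#' order of appearance, and joins per-atom force-field parameters from the
#' parameter table by `(residue_name, atom_name)`.
#'
#' @param path PDB file path.
#' @param params Parameter tibble from [read_param_table()] (or a path).
#' @param ligand Optional ligand residue name overriding auto-detection.
#' @return A [complex_system()] (reference conformation = the file's
#'   coordinates; no rotatable dihedrals — attach them separately if the
#'   DIH descriptor is wanted).
#' @export
read_structure <- function(path, params = read_param_table(), ligand = NULL) {
  if (is.character(params)) params <- read_param_table(params)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- as_tibble(pdb$atom)
  a <- a[!(a$resid %in% c(WATER_RESNAMES, ION_RESNAMES)), , drop = FALSE]
  if (!nrow(a)) {
    abort("No atoms left after removing waters/ions.",
          class = "diascore_selection_error")
  }
  if (is.null(ligand)) {
    het <- a[a$type == "HETATM", , drop = FALSE]
    if (!nrow(het)) {
      abort("No HETATM ligand candidate found; pass `ligand` explicitly.",
            class = "diascore_selection_error")
    }
    counts <- table(het$resid)
    ligand <- names(counts)[which.max(counts)]
  }
  is_lig <- a$resid == ligand
  if (!any(is_lig)) {
    abort(paste0("Ligand residue '", ligand, "' not present."),
          class = "diascore_selection_error")
  }
  key <- paste(a$resid, a$elety, sep = "/")
  pkey <- paste(params$residue_name, params$atom_name, sep = "/")
  hit <- match(key, pkey)
  if (anyNA(hit)) {
    abort(paste0("No parameters for atoms: ",
                 paste(unique(key[is.na(hit)])[1:min(5, sum(is.na(hit)))],
                       collapse = ", ")),
          class = "diascore_lookup_error")
  }
  # contiguous protein residue indices in order of appearance
  prot <- !is_lig
  rid <- paste(a$chain, a$resno, a$insert)
  res_index <- integer(nrow(a))
  res_index[prot] <- as.integer(factor(rid[prot], levels = unique(rid[prot])))
  res_index[is_lig] <- max(res_index[prot], 0L) + 1L
  atoms <- tibble(
    atom_id = seq_len(nrow(a)),
    residue_index = res_index,
    is_ligand = is_lig,
    charge = params$charge_e[hit],
    lj_re = params$rmin_half_A[hit],
    lj_eps = params$eps_kcal[hit],
    solv_param = params$solv_param[hit],
    radius = params$radius_A[hit]
  )
  complex_system(atoms, cbind(a$x, a$y, a$z))
}

#' Read a conformational ensemble from a multi-model PDB
#'
#' @param path Multi-model PDB path (a single-model file gives a one-frame
#'   ensemble).
#' @param system The [complex_system()] topology the frames belong to.
#' @param frame_interval Sampling interval, ps.
#' @return An [ensemble_frames()] object.
#' @export
read_trajectory <- function(path, system, frame_interval = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nat <- ncol(xyz) / 3
  if (nat != nrow(system$atoms)) {
    abort(paste0("Trajectory atom count (", nat,
                 ") does not match the system (", nrow(system$atoms), ")."),
          class = "diascore_shape_error")
  }
  frames <- lapply(seq_len(nrow(xyz)), function(k)
    matrix(xyz[k, ], ncol = 3, byrow = TRUE))
  ensemble_frames(system, frames, frame_interval)
}

#' Write a complex (optionally an ensemble) to PDB
#'
#' Protein atoms are written as ATOM records (residue `TOY`), ligand atoms
#' as HETATM (`LIG`), with unique per-atom names so the emitted parameter
#' table round-trips exactly. `write_ensemble_pdb()` wraps one PDB block
#' per frame in MODEL/ENDMDL records.
#'
#' @param system A [complex_system()].
#' @param path Output path.
#' @param coords Conformation to write (default reference).
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(system, path, coords = system$coords) {
  writeLines(pdb_block(system, coords), path)
  invisible(path)
}

#' @rdname write_complex_pdb
#' @param frames An [ensemble_frames()] object.
#' @export
write_ensemble_pdb <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames$frames)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(pdb_block(frames$system, frames$frames[[k]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# fixed-width PDB ATOM/HETATM records for one conformation
pdb_block <- function(system, coords) {
  at <- system$atoms
  sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          ifelse(at$is_ligand, "HETATM", "ATOM"),
          at$atom_id,
          toy_atom_names(system),
          ifelse(at$is_ligand, "LIG", "TOY"),
          "A",
          at$residue_index,
          coords[, 1], coords[, 2], coords[, 3], 1, 0)
}

# unique short atom names: A001.. for protein, L001.. for ligand
toy_atom_names <- function(system) {
  at <- system$atoms
  ifelse(at$is_ligand,
         sprintf("L%03d", cumsum(at$is_ligand)[at$atom_id]),
         sprintf("A%03d", cumsum(!at$is_ligand)[at$atom_id]))
}

#' Emit the parameter table matching a written toy PDB
#'
#' One row per atom, keyed by the unique names [write_complex_pdb()] uses,
#' so that [read_structure()] reconstructs the exact per-atom parameters.
#'
#' @param system A [complex_system()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(system, path) {
  at <- system$atoms
  d <- tibble(
    atom_name = toy_atom_names(system),
    residue_name = ifelse(at$is_ligand, "LIG", "TOY"),
    charge_e = at$charge,
    rmin_half_A = at$lj_re,
    eps_kcal = at$lj_eps,
    solv_param = at$solv_param,
    radius_A = at$radius
  )
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read / write paired solvated-vacuum force sets
#'
#' TSV with columns `atom_id`, `Fx_real`, `Fy_real`, `Fz_real`, `Fx_vac`,
#' `Fy_vac`, `Fz_vac` (kcal/mol/A), one row per protein atom.
#'
#' @param path TSV path.
#' @return For the reader: a list with `atom_id`, `F_real` and `F_vac`
#'   (n x 3 matrices).
#' @export
read_force_sets <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("atom_id", "Fx_real", "Fy_real", "Fz_real",
            "Fx_vac", "Fy_vac", "Fz_vac")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    abort(paste0("Force file is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "diascore_parameter_error")
  }
  list(atom_id = d$atom_id,
       F_real = as.matrix(d[, c("Fx_real", "Fy_real", "Fz_real")]),
       F_vac = as.matrix(d[, c("Fx_vac", "Fy_vac", "Fz_vac")]))
}

#' @rdname read_force_sets
#' @param forces Force tibble as produced by [make_toy_complex()].
#' @export
write_force_sets <- function(forces, path) {
  readr::write_tsv(forces, path)
  invisible(path)
}

#' Read / write complex feature records as JSON
#'
#' Features survive a write/read round trip value-identically (full double
#' precision is serialized).
#'
#' @param features Feature tibble ([extract_features()] rows).
#' @param path JSON path.
#' @return The reader returns a feature tibble.
#' @export
write_features <- function(features, path) {
  jsonlite::write_json(features, path, auto_unbox = FALSE, digits = I(17),
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- as_tibble(jsonlite::fromJSON(path))
  # all-null numeric columns come back logical; restore their type
  num_cols <- c("sum_vdw", "sum_ele", "sum_ele_scaled", "sum_fluct_vdw",
                "sum_fluct_ele", "S_ASA", "S_DIH", "S_VDW", "S_ELE",
                "dg_exptl")
  for (cl in intersect(num_cols, names(d))) {
    if (is.logical(d[[cl]])) d[[cl]] <- as.double(d[[cl]])
  }
  d
}

#' Read a feature dataset from TSV
#'
#' Columns `complex_id`, `dg_exptl`, and the feature columns used by the
#' chosen model (see [predict_dg()]).
#'
#' @param path TSV path.
#' @return Feature tibble.
#' @export
read_dataset <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_dataset
#' @param data Feature tibble.
#' @export
write_dataset <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Serialize fitted parameters to JSON and back
#'
#' @param params A [dia_params()] object.
#' @param path JSON path.
#' @return The reader returns a [dia_params()] object.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::fromJSON(path)
  dia_params(alpha = p$alpha, alpha2 = p$alpha2, beta = p$beta,
             beta2 = p$beta2, tau = p$tau,
             x = p$x %||% NA_real_,
             vdw_form = p$vdw_form, property = p$property,
             model_kind = p$model_kind,
             tau_extra = if (length(p$tau_extra)) unlist(p$tau_extra))
}

#' Write a cross-validation report (JSON + TSV twin)
#'
#' `<prefix>.json` carries predictions, metrics and parameters;
#' `<prefix>.tsv` the per-complex prediction table for diffing.
#'
#' @param cv A `dia_cv` object from [loo_cv()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_cv_result <- function(cv, prefix) {
  json_path <- paste0(prefix, ".json")
  tsv_path <- paste0(prefix, ".tsv")
  jsonlite::write_json(
    list(mae = cv$mae, pearson_r = cv$pearson_r,
         params = unclass(cv$fit$params),
         predictions = cv$predictions),
    json_path, auto_unbox = TRUE, digits = I(17), na = "null",
    dataframe = "rows")
  readr::write_tsv(cv$predictions, tsv_path)
  invisible(c(json_path, tsv_path))
}
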