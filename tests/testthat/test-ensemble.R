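make_two_frame_ensemble <- function(seed = 21, delta = 0.5) {
  sys <- random_small_system(seed)
  f2 <- sys$coords
  f2[nrow(f2), 1] <- f2[nrow(f2), 1] + delta
  ensemble_frames(sys, list(sys$coords, f2))
}

test_that("a single frame gives that frame's energies and zero fluctuation", {
  sys <- random_small_system(20)
  ens <- ensemble_frames(sys, list(sys$coords))
  prof <- ensemble_interaction_profile(ens, "12-6")
  ref <- residue_ligand_energies(sys, form = "12-6")
  expect_equal(prof$mean_vdw, ref$e_vdw)
  expect_equal(prof$mean_ele, ref$e_ele)
  expect_equal(prof$fluct_vdw, rep(0, sys$residue_count))
  expect_equal(prof$fluct_ele, rep(0, sys$residue_count))
})

test_that("duplicating frames leaves the profile unchanged", {
  ens <- make_two_frame_ensemble()
  prof1 <- ensemble_interaction_profile(ens, "8-4")
  ens3 <- ensemble_frames(ens$system,
                          rep(ens$frames, 3))
  expect_equal(ensemble_interaction_profile(ens3, "8-4"), prof1)
})

test_that("fluctuation is the population SD over frames", {
  # two frames give fluctuation = |E1 - E2| / 2 per residue
  ens <- make_two_frame_ensemble(delta = 1.0)
  e1 <- residue_ligand_energies(ens$system, ens$frames[[1]], "12-6")
  e2 <- residue_ligand_energies(ens$system, ens$frames[[2]], "12-6")
  prof <- ensemble_interaction_profile(ens, "12-6")
  expect_equal(prof$mean_vdw, (e1$e_vdw + e2$e_vdw) / 2)
  expect_equal(prof$fluct_vdw, abs(e1$e_vdw - e2$e_vdw) / 2)
  expect_equal(prof$fluct_ele, abs(e1$e_ele - e2$e_ele) / 2)
  expect_true(all(prof$fluct_vdw >= 0))
})

test_that("ensembles reject empty frame lists and atom-count mismatches", {
  sys <- random_small_system(22)
  expect_error(ensemble_frames(sys, list()),
               class = "diascore_empty_ensemble")
  expect_error(ensemble_frames(sys, list(sys$coords[-1, , drop = FALSE])),
               class = "diascore_shape_error")
})

test_that("rigid ensembles give zero for every entropy descriptor", {
  toy <- make_toy_complex(seed = 5, n_residues = 4, atoms_per_residue = 4,
                          n_ligand_atoms = 5, n_frames = 4, jitter = 0)
  for (p in c("ASA", "DIH", "VDW", "ELE")) {
    d <- entropy_descriptor(toy$frames, p, n_points = 240)
    # exactly repeated frames leave only last-ulp circular-statistics noise
    expect_lt(d$value, 1e-6)
  }
})

test_that("entropy descriptors are frame-order invariant and non-negative", {
  toy <- make_toy_complex(seed = 6, n_residues = 4, atoms_per_residue = 4,
                          n_ligand_atoms = 5, n_frames = 6, jitter = 0.3)
  rev_ens <- ensemble_frames(toy$system, rev(toy$frames$frames))
  for (p in c("ASA", "DIH", "VDW", "ELE")) {
    v1 <- entropy_descriptor(toy$frames, p, n_points = 240)$value
    v2 <- entropy_descriptor(rev_ens, p, n_points = 240)$value
    expect_equal(v1, v2)
    expect_gte(v1, 0)
  }
})

test_that("dihedral fluctuation uses circular statistics across the wrap", {
  # a torsion alternating +179/-179 degrees is a 2-degree wobble, not 358
  sys <- random_small_system(23, n_res = 1, apr = 4, n_lig = 4)
  base <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.4, 0), c(3.7, 1.4, 0),
                sys$coords[5:8, ])
  # atoms 1-3 in the xy-plane along the 2->3 bond; atom 4 is rotated about
  # that bond so the 1-2-3-4 torsion takes the requested value
  frame_for <- function(deg) {
    th <- deg * pi / 180
    b <- base
    axis <- (b[3, ] - b[2, ]) / sqrt(sum((b[3, ] - b[2, ])^2))
    # reference direction perpendicular to the axis, in-plane
    v0 <- c(1.5, 0, 0) - axis * sum(axis * c(1.5, 0, 0))
    cr <- function(a, v) c(a[2] * v[3] - a[3] * v[2],
                           a[3] * v[1] - a[1] * v[3],
                           a[1] * v[2] - a[2] * v[1])
    b[4, ] <- b[3, ] + v0 * cos(th) + cr(axis, v0) * sin(th)
    b
  }
  sys2 <- complex_system(sys$atoms, base, list(1:4))
  f1 <- frame_for(179); f2 <- frame_for(-179)
  ens <- ensemble_frames(sys2, list(f1, f2, f1, f2))
  v <- entropy_descriptor(ens, "DIH")$value
  expect_lt(v, 5 * pi / 180)   # near 1-2 degrees, far from ~179
  expect_gt(v, 0)
})

test_that("DIH without declared dihedrals is a configuration error", {
  sys <- random_small_system(24)
  ens <- ensemble_frames(sys, list(sys$coords, sys$coords))
  expect_error(entropy_descriptor(ens, "DIH"),
               class = "diascore_configuration_error")
})

test_that("a unit dielectric map reproduces unscaled electrostatics exactly", {
  ens <- make_two_frame_ensemble(25)
  prot_ids <- ens$system$atoms$atom_id[!ens$system$atoms$is_ligand]
  unit <- tibble::tibble(atom_id = prot_ids, eps_eff = 1)
  prof <- scaled_ele_profile(ens, unit, form = "12-6")
  expect_identical(prof$mean_ele_scaled, prof$mean_ele)
})

test_that("uniform and per-atom dielectric scaling match the oracle", {
  ens <- make_two_frame_ensemble(26)
  sys <- ens$system
  prot_ids <- sys$atoms$atom_id[!sys$atoms$is_ligand]
  half <- tibble::tibble(atom_id = prot_ids, eps_eff = 2)
  prof <- scaled_ele_profile(ens, half)
  expect_equal(prof$mean_ele_scaled, prof$mean_ele / 2)
  # mixed per-atom factors against the brute-force pairwise oracle
  withr::with_seed(27, {
    mixed <- tibble::tibble(atom_id = prot_ids,
                            eps_eff = runif(length(prot_ids), 1, 6))
  })
  prof2 <- scaled_ele_profile(ens, mixed)
  eps_vec <- rep(1, nrow(sys$atoms))
  eps_vec[mixed$atom_id] <- mixed$eps_eff
  want <- (brute_force_residue_energies(sys, ens$frames[[1]], "12-6", eps_vec)$e_ele +
           brute_force_residue_energies(sys, ens$frames[[2]], "12-6", eps_vec)$e_ele) / 2
  expect_equal(prof2$mean_ele_scaled, want, tolerance = 1e-9)
})

test_that("a dielectric map missing protein atoms is a coverage error", {
  ens <- make_two_frame_ensemble(28)
  bad <- tibble::tibble(atom_id = 1L, eps_eff = 2)
  expect_error(scaled_ele_profile(ens, bad),
               class = "diascore_coverage_error")
})

test_that("extract_features aggregates profile sums and descriptors", {
  toy <- make_toy_complex(seed = 8, n_residues = 4, atoms_per_residue = 4,
                          n_ligand_atoms = 5, n_frames = 3, jitter = 0.2)
  dmap <- effective_dielectric(
    as.matrix(toy$forces[, c("Fx_real", "Fy_real", "Fz_real")]),
    as.matrix(toy$forces[, c("Fx_vac", "Fy_vac", "Fz_vac")]),
    x = 0.6, atom_id = toy$forces$atom_id)
  f <- extract_features(toy$frames, form = "8-4", dmap = dmap,
                        complex_id = "toy8", n_points = 240)
  prof <- ensemble_interaction_profile(toy$frames, "8-4", dmap = dmap)
  expect_equal(f$sum_vdw, sum(prof$mean_vdw))
  expect_equal(f$sum_ele, sum(prof$mean_ele))
  expect_equal(f$sum_ele_scaled, sum(prof$mean_ele_scaled))
  expect_equal(f$sum_fluct_vdw, sum(prof$fluct_vdw))
  expect_equal(f$S_VDW,
               entropy_descriptor(toy$frames, "VDW", "8-4")$value)
  expect_identical(f$n_frames, 3L)
  expect_identical(f$vdw_form, "8-4")
  # scaled electrostatics shrink in magnitude under eps >= 1
  expect_lte(abs(f$sum_ele_scaled), abs(f$sum_ele) + 1e-9)
})
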