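# Independent oracles and tiny-system builders shared across tests.
# Oracles deliberately use naive double loops / grid integration so they
# share no code path with the package internals they check.

# naive O(N^2) per-residue energy sum over explicit pair loops
brute_force_residue_energies <- function(system, coords, form,
                                         eps_atom = NULL) {
  at <- system$atoms
  k_coul <- 332.0637
  nm <- switch(form, "12-6" = c(12, 6), "9-6" = c(9, 6),
               "8-4" = c(8, 4), "6-3" = c(6, 3))
  out <- data.frame(residue_index = seq_len(system$residue_count),
                    e_vdw = 0, e_ele = 0)
  for (i in which(!at$is_ligand)) {
    for (j in which(at$is_ligand)) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      Re <- at$lj_re[i] + at$lj_re[j]
      eps <- sqrt(at$lj_eps[i] * at$lj_eps[j])
      q <- Re / r
      ev <- eps / (nm[1] - nm[2]) * (nm[2] * q^nm[1] - nm[1] * q^nm[2])
      ee <- k_coul * at$charge[i] * at$charge[j] / r
      if (!is.null(eps_atom)) ee <- ee / eps_atom[i]
      ri <- at$residue_index[i]
      out$e_vdw[ri] <- out$e_vdw[ri] + ev
      out$e_ele[ri] <- out$e_ele[ri] + ee
    }
  }
  out
}

# accessible area of sphere 1 (radius r1 + probe) against sphere 2 by
# latitude-band grid integration, independent of the sphere-point method
grid_two_sphere_area <- function(c1, r1, c2, r2, probe, n_theta = 2000,
                                 n_phi = 2000) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  dA <- R1^2 * sin(theta) * (pi / n_theta) * (2 * pi / n_phi)
  total <- 0
  for (t in seq_len(n_theta)) {
    p <- cbind(R1 * sin(theta[t]) * cos(phi),
               R1 * sin(theta[t]) * sin(phi),
               R1 * cos(theta[t]))
    p <- sweep(p, 2, c1, `+`)
    d2 <- rowSums(sweep(p, 2, c2, `-`)^2)
    total <- total + dA[t] * sum(d2 >= R2^2)
  }
  total
}

# random small complex with given counts; all parameters positive-valid
random_small_system <- function(seed, n_res = 3, apr = 3, n_lig = 4) {
  withr::with_seed(seed, {
    n_prot <- n_res * apr
    n <- n_prot + n_lig
    repeat {
      coords <- matrix(runif(3 * n, -6, 6), n, 3)
      if (min(dist(coords)) > 1.0) break
    }
    atoms <- tibble::tibble(
      atom_id = seq_len(n),
      residue_index = c(rep(seq_len(n_res), each = apr), rep(n_res + 1L, n_lig)),
      is_ligand = c(rep(FALSE, n_prot), rep(TRUE, n_lig)),
      charge = rnorm(n, sd = 0.3),
      lj_re = runif(n, 1.4, 2.1),
      lj_eps = runif(n, 0.02, 0.25),
      solv_param = runif(n, 0.005, 0.03),
      radius = runif(n, 1.2, 1.9)
    )
    complex_system(atoms, coords)
  })
}

# benchmark-scale generating parameters reused across model tests
reference_params <- function(model_kind = "diav") {
  dia_params(alpha = 0.0378, alpha2 = 0.0093, beta = 0.0082,
             beta2 = -0.0011, tau = -2.4178e-4,
             x = if (model_kind == "dias") 0.6 else NA_real_,
             vdw_form = "8-4", property = "ASA", model_kind = model_kind)
}
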