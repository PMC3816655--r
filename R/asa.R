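#' Shrake-Rupley accessible surface area
#'
#' Per-atom solvent-accessible surface area by the classic sphere-point
#' method: a deterministic quasi-uniform point set (Fibonacci lattice) is
#' placed on each atom's solvent-expanded sphere of radius `r + probe`, and
#' the accessible fraction is the fraction of points not buried inside any
#' neighbouring atom's expanded sphere.
#'
#' @param coords Numeric matrix `n x 3`, Angstrom.
#' @param radii Per-atom van der Waals radii, Angstrom.
#' @param probe Probe (solvent) radius, Angstrom; water is 1.4.
#' @param n_points Sphere points per atom; accuracy is roughly O(1/n).
#' @return Numeric vector of per-atom areas in Angstrom^2, each in
#'   `[0, 4*pi*(r+probe)^2]`.
#' @examples
#' shrake_rupley_asa(matrix(0, 1, 3), radii = 1.5)  # isolated sphere
#' @export
shrake_rupley_asa <- function(coords, radii, probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n || any(!is.finite(radii)) || any(radii <= 0)) {
    abort("`radii` must be positive, finite and match the atom count.",
          class = "diascore_invalid_parameter")
  }
  if (n_points < 60) {
    abort("`n_points` must be >= 60.", class = "diascore_invalid_parameter")
  }
  # duplicate coordinates make burial ill-defined; flag but keep computing
  if (n > 1 && anyDuplicated(round(coords, 6))) {
    warn("Distinct atoms share identical coordinates; ASA is degenerate there.",
         class = "diascore_degenerate_geometry")
  }
  pts <- fibonacci_sphere(n_points)
  rext <- radii + probe
  rext2 <- rext^2
  # neighbour search radius: spheres can only intersect within ri + rj
  d2 <- as.matrix(stats::dist(coords))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    cand <- which(d2[i, ] < (rext[i] + rext)^2 & seq_len(n) != i)
    sp <- sweep(pts * rext[i], 2, coords[i, ], `+`)
    if (length(cand) == 0L) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in cand) {
        dj <- sweep(sp, 2, coords[j, ], `-`)
        buried <- buried | (rowSums(dj^2) < rext2[j])
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    area[i] <- 4 * pi * rext2[i] * acc / n_points
  }
  area
}

# deterministic quasi-uniform unit-sphere points (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Total (optionally solvation-weighted) accessible surface area
#'
#' The scalar ASA property of one conformation of a complex: the sum of
#' per-atom Shrake-Rupley areas, or, in weighted mode, the solvation energy
#' proxy `sum(solv_param * ASA_atom)`.
#'
#' @param system A [complex_system()] supplying radii and solvation
#'   parameters.
#' @param coords Conformation (default: reference coordinates).
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere points per atom.
#' @param weighted If `TRUE`, weight each atom's area by its atomic
#'   solvation parameter (result in kcal/mol); otherwise plain Angstrom^2.
#' @return A single number.
#' @export
asa_property <- function(system, coords = system$coords, probe = 1.4,
                         n_points = 960, weighted = FALSE) {
  a <- shrake_rupley_asa(coords, system$atoms$radius, probe, n_points)
  if (weighted) sum(system$atoms$solv_param * a) else sum(a)
}
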