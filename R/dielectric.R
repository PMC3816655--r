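#' Effective dielectric constants from solvated vs vacuum forces
#'
#' In a binding pocket the electrostatic screening varies from point to
#' point (protein interior ~2-4, bulk water ~78.5). A per-atom effective
#' dielectric constant is estimated from the ratio of the electrostatic
#' force each protein atom feels in explicit solvent (`F_real`) to the
#' force in vacuum (`F_vac`):
#' \describe{
#'   \item{mode 19 (default)}{raw ratio = `|F_vac| / |F_real|` on vector
#'     magnitudes.}
#'   \item{mode 18}{raw ratio = projection of `F_vac` onto the `F_real`
#'     direction, divided by `|F_real|` (magnitude of the signed ratio).}
#' }
#' The raw ratio blows up when `|F_real|` is nearly zero, so it is damped
#' with a regularizer `x`:
#' \deqn{\epsilon_{eff} = \max\!\left(1,\;
#'   \frac{|F_{vac}| + x\bar F}{|F_{real}| + x\bar F}\right)}
#' with \eqn{\bar F} the mean `|F_vac|` over atoms. This is finite for any
#' `x > 0`, reduces to the raw ratio when forces are strong, and is clipped
#' to the physical bound `eps_eff >= 1`.
#'
#' @param F_real Numeric matrix `n x 3`: per-atom electrostatic force in
#'   explicit solvent (kcal/mol/A).
#' @param F_vac Numeric matrix `n x 3`: same atoms, in vacuum.
#' @param x Non-negative regularizer (dimensionless); the benchmark optimum
#'   is 0.6.
#' @param mode `19` (magnitude ratio) or `18` (projection ratio).
#' @param atom_id Optional atom ids for the output (default `1:n`).
#' @return Tibble with columns `atom_id`, `eps_raw`, `eps_eff`
#'   (`eps_eff >= 1`, finite).
#' @examples
#' F <- matrix(rnorm(30), 10, 3)
#' effective_dielectric(F, 3 * F, x = 0.6)  # uniform screening factor 3
#' @export
effective_dielectric <- function(F_real, F_vac, x = 0.6, mode = 19,
                                 atom_id = NULL) {
  F_real <- as.matrix(F_real); F_vac <- as.matrix(F_vac)
  if (!identical(dim(F_real), dim(F_vac)) || ncol(F_real) != 3) {
    abort("`F_real` and `F_vac` must be n x 3 matrices of equal size.",
          class = "diascore_shape_error")
  }
  if (!is.finite(x) || x < 0) {
    abort("`x` must be finite and >= 0.", class = "diascore_invalid_parameter")
  }
  if (!mode %in% c(18, 19)) {
    abort("`mode` must be 18 or 19.", class = "diascore_invalid_parameter")
  }
  mag_real <- sqrt(rowSums(F_real^2))
  mag_vac <- sqrt(rowSums(F_vac^2))
  num <- if (mode == 19) {
    mag_vac
  } else {
    # |projection of F_vac on unit F_real|; falls back to |F_vac| where
    # F_real vanishes and no direction exists
    proj <- abs(rowSums(F_vac * F_real)) / ifelse(mag_real > 0, mag_real, 1)
    ifelse(mag_real > 0, proj, mag_vac)
  }
  eps_raw <- ifelse(mag_real > 0, num / mag_real, Inf)
  fbar <- mean(mag_vac)
  damp <- x * fbar
  eps_eff <- if (damp > 0) {
    pmax(1, (num + damp) / (mag_real + damp))
  } else {
    pmax(1, ifelse(mag_real > 0, num / mag_real, Inf))
  }
  tibble(
    atom_id = atom_id %||% seq_len(nrow(F_real)),
    eps_raw = eps_raw,
    eps_eff = eps_eff
  )
}
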