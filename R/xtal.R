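#' Triclinic unit-cell volume
#'
#' `V = a*b*c * sqrt(1 - cos^2(alpha) - cos^2(beta) - cos^2(gamma)
#'  + 2*cos(alpha)*cos(beta)*cos(gamma))`, valid for any crystal system.
#'
#' @param a,b,c Cell edge lengths, Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles, degrees, in (0, 180). Default 90.
#' @return Cell volume, cubic Angstrom.
#' @export
#' @examples
#' cell_volume(75.94, 208.22, 255.29)
cell_volume <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) {
    abort("Cell lengths must be > 0.", class = "lcp_domain_error")
  }
  if (any(c(alpha, beta, gamma) <= 0 | c(alpha, beta, gamma) >= 180)) {
    abort("Cell angles must lie in (0, 180) degrees.",
          class = "lcp_domain_error")
  }
  ca <- cos(alpha * pi / 180)
  cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  rad <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (rad <= 0) {
    abort("Degenerate cell metric: the angle combination encloses no volume.",
          class = "lcp_invalid_cell_error")
  }
  a * b * c * sqrt(rad)
}

#' General-position multiplicity of common space-group settings
#'
#' Small lookup used to turn "one assembly per asymmetric unit" into the
#' total count per cell; callers with other settings supply `z_total`
#' directly to [matthews_coefficient()].
#'
#' @param space_group Space-group symbol, e.g. `"C2221"` or `"C222(1)"`.
#' @return Integer multiplicity.
#' @export
#' @examples
#' space_group_multiplicity("C2221")
space_group_multiplicity <- function(space_group) {
  key <- toupper(gsub("[^0-9A-Za-z]", "", space_group))
  tab <- c(P1 = 1L, P21 = 2L, C2 = 4L, P212121 = 4L, C2221 = 8L,
           P21212 = 4L, I222 = 8L, F222 = 16L, P3121 = 6L, P6122 = 12L,
           I4122 = 16L, P43212 = 8L)
  if (!key %in% names(tab)) {
    abort(paste0("No multiplicity on record for '", space_group,
                 "'; pass z_total explicitly."),
          class = "lcp_validation_error")
  }
  tab[[key]]
}

#' Matthews coefficient and solvent fraction
#'
#' `V_M = V / (z_total * mw)` in cubic Angstrom per Dalton, and
#' `solvent_fraction = 1 - vbar / (0.6022 * V_M)`, where 1/0.6022 converts
#' Dalton to cubic Angstrom through Avogadro's number and `vbar` is the
#' protein partial specific volume (conventional 0.74 cm^3/g). A solvent
#' fraction outside (0, 1) is reported as computed with `plausible = FALSE`
#' rather than raised as an error.
#'
#' @param volume Unit-cell volume, cubic Angstrom (see [cell_volume()]).
#' @param z_total Number of assembly copies per unit cell (general-position
#'   multiplicity times assemblies per asymmetric unit).
#' @param mw Assembly molecular weight, Dalton.
#' @param vbar Partial specific volume, cm^3/g, in (0.5, 1.0). Default 0.74.
#' @return One-row tibble: `v_m` (A^3/Da), `solvent_fraction`, `plausible`.
#' @export
#' @examples
#' v <- cell_volume(75.94, 208.22, 255.29)
#' matthews_coefficient(v, z_total = 8, mw = 174000)
matthews_coefficient <- function(volume, z_total, mw, vbar = 0.74) {
  if (volume <= 0 || z_total < 1 || mw <= 0) {
    abort("`volume`, `z_total` and `mw` must be positive (z_total >= 1).",
          class = "lcp_domain_error")
  }
  if (vbar <= 0.5 || vbar >= 1.0) {
    abort("`vbar` must lie in (0.5, 1.0) cm^3/g.", class = "lcp_domain_error")
  }
  v_m <- volume / (z_total * mw)
  solvent <- 1 - vbar / (0.6022 * v_m)
  plausible <- solvent >= 0 && solvent < 1
  if (!plausible) {
    warn(sprintf("Solvent fraction %.3f outside (0, 1); check z_total/mw.",
                 solvent))
  }
  tibble::tibble(v_m = v_m, solvent_fraction = solvent, plausible = plausible)
}
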