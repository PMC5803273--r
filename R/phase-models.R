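#' Mesophase reflection models
#'
#' Allowed Bragg-reflection position ratios for the mesophases handled by the
#' indexing routines. For each phase the observable peak positions are
#' `q_i = k * m_i` for a single scale factor `k`, with multipliers `m_i`:
#' the square roots of the allowed h^2+k^2+l^2 sums for the bicontinuous
#' cubics, integers for the lamellar stack, and 1, sqrt(3), 2, sqrt(7) for the
#' inverse hexagonal phase. The scale relates to the lattice parameter by
#' `a = 2*pi/k` (cubic), repeat distance `d = 2*pi/k` (lamellar) and
#' `a_hex = 4*pi/(k*sqrt(3))` (hexagonal).
#'
#' @param names Character vector of phase names to return. Default: the
#'   cubic and lamellar phases; `"HII"` is available but not a default
#'   indexing candidate.
#' @return A tibble with columns `phase`, `family` and `multipliers`
#'   (list-column of ascending numeric vectors).
#' @export
#' @examples
#' phase_models()
#' phase_models(c("Pn3m", "La"))
phase_models <- function(names = c("Ia3d", "Pn3m", "Im3m", "La")) {
  all <- tibble::tibble(
    phase = c("Ia3d", "Pn3m", "Im3m", "La", "HII"),
    family = c("cubic", "cubic", "cubic", "lamellar", "hexagonal"),
    multipliers = list(
      sqrt(c(6, 8, 14, 16, 20, 22, 24, 26)),
      sqrt(c(2, 3, 4, 6, 8, 9, 10, 11)),
      sqrt(c(2, 4, 6, 8, 10, 12, 14, 16)),
      c(1, 2, 3, 4),
      c(1, sqrt(3), 2, sqrt(7))
    )
  )
  bad <- setdiff(names, all$phase)
  if (length(bad) > 0) {
    abort(paste0("Unknown phase(s): ", paste(bad, collapse = ", ")),
          class = "lcp_validation_error")
  }
  all[match(names, all$phase), ]
}

#' Lattice parameter from the reflection scale factor
#'
#' @param k Scale factor such that peaks sit at `k * m_i` (1/Angstrom).
#' @param family `"cubic"`, `"lamellar"` or `"hexagonal"`.
#' @return Lattice parameter (cubic cell edge, lamellar repeat, or hexagonal
#'   cell edge), Angstrom.
#' @keywords internal
scale_to_lattice <- function(k, family) {
  switch(family,
    cubic = 2 * pi / k,
    lamellar = 2 * pi / k,
    hexagonal = 4 * pi / (k * sqrt(3)),
    abort(paste0("Unknown family: ", family), class = "lcp_validation_error")
  )
}

#' Minimal-surface constants of the bicontinuous cubic phases
#'
#' Per-phase constants of the triply periodic minimal surfaces underlying the
#' bicontinuous cubic mesophases: `A0`, the ratio of minimal-surface area per
#' unit cell to (cell volume)^(2/3); `chi`, the Euler-Poincare characteristic
#' of the surface per unit cell; and `c_chan`, the coefficient in the
#' water-channel radius relation `r = c_chan * a - l`.
#'
#' @return A tibble with columns `phase`, `A0`, `chi`, `c_chan`.
#' @export
#' @examples
#' cubic_phase_constants()
cubic_phase_constants <- function() {
  tibble::tibble(
    phase = c("Ia3d", "Pn3m", "Im3m"),
    A0 = c(3.091, 1.919, 2.345),
    chi = c(-8, -2, -4),
    c_chan = c(0.248, 0.391, 0.305)
  )
}

.cubic_constants_row <- function(phase) {
  tab <- cubic_phase_constants()
  i <- match(phase, tab$phase)
  if (is.na(i)) {
    abort(paste0("`phase` must be one of ", paste(tab$phase, collapse = ", "),
                 "; got '", phase, "'."),
          class = "lcp_validation_error")
  }
  tab[i, ]
}
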