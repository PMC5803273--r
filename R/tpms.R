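#' Sample composition of a lipid mesophase
#'
#' Bundles the weight fractions and densities needed to compute the lipid
#' volume fraction. The lipid mix (monoacylglycerol host plus any added
#' phospholipid) is treated as a single component with one density; the
#' default 0.982 g/cm^3 is the monopalmitolein value.
#'
#' @param water_wt_frac Water weight fraction of the total sample, in [0, 1].
#' @param dspg_wt_frac_of_lipid Phospholipid weight fraction of the lipid mix,
#'   in [0, 1]. Carried as metadata; it does not enter the volume-fraction
#'   computation, which uses the single lipid density.
#' @param lipid_density Lipid density, g/cm^3 (default 0.982).
#' @param water_density Water density, g/cm^3 (default 1.0).
#' @return A one-row tibble of class `lcp_composition`.
#' @export
#' @examples
#' composition(water_wt_frac = 0.80)
composition <- function(water_wt_frac, dspg_wt_frac_of_lipid = 0,
                        lipid_density = 0.982, water_density = 1.0) {
  if (any(water_wt_frac < 0 | water_wt_frac > 1) ||
      any(dspg_wt_frac_of_lipid < 0 | dspg_wt_frac_of_lipid > 1)) {
    abort("Weight fractions must lie in [0, 1].", class = "lcp_domain_error")
  }
  if (any(lipid_density <= 0) || any(water_density <= 0)) {
    abort("Densities must be > 0.", class = "lcp_domain_error")
  }
  out <- tibble::tibble(water_wt_frac = water_wt_frac,
                        lipid_wt_frac = 1 - water_wt_frac,
                        dspg_wt_frac_of_lipid = dspg_wt_frac_of_lipid,
                        lipid_density = lipid_density,
                        water_density = water_density)
  class(out) <- c("lcp_composition", class(out))
  out
}

#' Lipid volume fraction from weight fractions and densities
#'
#' `phi = (m_L / rho_L) / (m_L / rho_L + m_W / rho_W)` with `m_L`, `m_W` the
#' lipid and water weight fractions. The boundary compositions return the
#' boundary values (water 0 -> phi = 1; water 1 -> phi = 0) without error.
#'
#' @param comp A [composition()] (or any data frame with its columns).
#' @return Numeric vector of lipid volume fractions in [0, 1].
#' @export
#' @examples
#' lipid_volume_fraction(composition(0.80))  # ~0.2029
lipid_volume_fraction <- function(comp) {
  v_l <- comp$lipid_wt_frac / comp$lipid_density
  v_w <- comp$water_wt_frac / comp$water_density
  v_l / (v_l + v_w)
}

# stationary point of phi(x) = 2*A0*x + (4/3)*pi*chi*x^3 on x > 0 (chi < 0):
# the largest x (= l/a) at which the cubic is still invertible
.x_star <- function(A0, chi) sqrt(-A0 / (2 * pi * chi))

.phi_of_x <- function(x, A0, chi) 2 * A0 * x + (4 / 3) * pi * chi * x^3

#' Maximum lipid volume fraction representable by a cubic phase model
#'
#' The value of the minimal-surface volume relation at its stationary point;
#' above it the relation has no physical root for the chain length.
#'
#' @param phase Cubic phase name: `"Ia3d"`, `"Pn3m"` or `"Im3m"`.
#' @return The maximum admissible lipid volume fraction (may exceed 1 for
#'   some phases, in which case all physical compositions are admissible).
#' @export
phi_max <- function(phase) {
  k <- .cubic_constants_row(phase)
  .phi_of_x(.x_star(k$A0, k$chi), k$A0, k$chi)
}

#' Solve the minimal-surface volume relation for the lipid chain length
#'
#' Inverts `phi = 2 * A0 * (l/a) + (4/3) * pi * chi * (l/a)^3` for the unique
#' root `x = l/a` in `(0, x*)`, where `x* = sqrt(-A0 / (2 * pi * chi))` is the
#' stationary point of the cubic; on that branch the relation is strictly
#' increasing, so chain length is monotone in the volume fraction. Bracketed
#' root finding ([stats::uniroot()]) is run to a residual below 1e-12.
#'
#' @param phi Lipid volume fraction, in (0, `phi_max(phase)`).
#' @param a Lattice parameter, Angstrom (> 0).
#' @param phase Cubic phase name: `"Ia3d"`, `"Pn3m"` or `"Im3m"`.
#' @return Chain length `l = x * a`, Angstrom.
#' @export
#' @examples
#' solve_chain_length(0.2029, 525, "Ia3d")  # ~17.3
solve_chain_length <- function(phi, a, phase) {
  k <- .cubic_constants_row(phase)
  if (any(a <= 0)) abort("`a` must be > 0.", class = "lcp_domain_error")
  pm <- phi_max(phase)
  if (any(phi <= 0)) {
    abort("`phi` must be > 0.", class = "lcp_domain_error")
  }
  if (any(phi >= pm)) {
    abort(sprintf(
      "`phi` = %.4f has no physical root for %s: the relation saturates at phi_max = %.4f.",
      max(phi), phase, pm), class = "lcp_no_root_error")
  }
  xs <- .x_star(k$A0, k$chi)
  x <- vapply(phi, function(p) {
    uniroot(function(x) .phi_of_x(x, k$A0, k$chi) - p,
            lower = 0, upper = xs, tol = .Machine$double.eps^0.75,
            f.lower = -p)$root
  }, numeric(1))
  x * a
}

#' Water-channel radius of a bicontinuous cubic phase
#'
#' `r = c_chan * a - l` with the phase-specific channel coefficient
#' (0.248 for Ia3d, 0.391 for Pn3m, 0.305 for Im3m).
#'
#' @param a Lattice parameter, Angstrom.
#' @param l Lipid chain length, Angstrom; must satisfy `l < c_chan * a`.
#' @param phase Cubic phase name.
#' @return Channel radius, Angstrom.
#' @export
#' @examples
#' water_channel_radius(525, 17.34, "Ia3d")  # ~112.9
water_channel_radius <- function(a, l, phase) {
  k <- .cubic_constants_row(phase)
  if (any(a <= 0)) abort("`a` must be > 0.", class = "lcp_domain_error")
  r <- k$c_chan * a - l
  if (any(r <= 0)) {
    abort(sprintf(
      "Chain length l = %.3f A >= %.3f * a: the %s geometry leaves no water channel.",
      max(l), k$c_chan, phase), class = "lcp_no_channel_error")
  }
  r
}

#' Water-channel geometry from lattice parameter and composition
#'
#' Full chain: lipid volume fraction from the composition, chain length from
#' the minimal-surface volume relation at the measured lattice parameter, then
#' channel radius `r = c_chan * a - l` and diameter `d_w = 2 * r`.
#'
#' @param a Lattice parameter measured by SAXS, Angstrom.
#' @param comp A [composition()].
#' @param phase Cubic phase name: `"Ia3d"`, `"Pn3m"` or `"Im3m"`.
#' @return A one-row tibble: `phase`, `a`, `phi`, `l`, `r`, `d_w` (all
#'   lengths in Angstrom).
#' @export
#' @examples
#' channel_geometry(525, composition(0.80), "Ia3d")  # d_w ~ 226
channel_geometry <- function(a, comp, phase) {
  phi <- lipid_volume_fraction(comp)
  l <- solve_chain_length(phi, a, phase)
  r <- water_channel_radius(a, l, phase)
  tibble::tibble(phase = phase, a = a, phi = phi, l = l, r = r, d_w = 2 * r)
}

#' Smallest lattice parameter providing a target water-channel diameter
#'
#' For fixed composition and phase the channel diameter is strictly increasing
#' in the lattice parameter, so the inverse design problem — how large must the
#' unit cell be for a guest of a given size — is solved by monotone bisection
#' on `a`.
#'
#' @param target_d Required channel diameter, Angstrom (> 0).
#' @param comp A [composition()].
#' @param phase Cubic phase name.
#' @param a_max Upper search bound for the lattice parameter (default 5000 A).
#' @param tol Absolute bisection tolerance on `a`, Angstrom (default 1e-6).
#' @return The [channel_geometry()] row at the minimal lattice parameter.
#' @export
#' @examples
#' min_lattice_for_channel(226, composition(0.80), "Ia3d")  # a ~ 525
min_lattice_for_channel <- function(target_d, comp, phase, a_max = 5000,
                                    tol = 1e-6) {
  if (target_d <= 0) abort("`target_d` must be > 0.",
                           class = "lcp_domain_error")
  phi <- lipid_volume_fraction(comp)
  if (phi >= phi_max(phase)) {
    abort("Composition exceeds the phase's maximum lipid volume fraction; no lattice can host the channel.",
          class = "lcp_no_solution_error")
  }
  d_at <- function(a) channel_geometry(a, comp, phase)$d_w
  # d_w scales linearly with a at fixed phi (x = l/a depends on phi only),
  # so any positive a gives d_w > 0 and the bound check is a formality
  if (d_at(a_max) < target_d) {
    abort(sprintf("target_d = %.1f A not reachable below a = %.0f A.",
                  target_d, a_max), class = "lcp_no_solution_error")
  }
  lo <- tol
  hi <- a_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (d_at(mid) >= target_d) hi <- mid else lo <- mid
  }
  channel_geometry(hi, comp, phase)
}
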