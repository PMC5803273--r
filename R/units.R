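#' Scattering-geometry unit conversions
#'
#' Conversions between the scattering vector magnitude Q, real-space repeat
#' distance (d-spacing), photon wavelength/energy and scattering angle, under
#' the small-angle convention Q = (4 * pi / lambda) * sin(theta) with 2 * theta
#' the scattering angle, so that d = 2 * pi / Q.
#'
#' @param q Scattering vector magnitude(s), 1/Angstrom. Must be > 0.
#' @param d d-spacing(s), Angstrom. Must be > 0.
#' @param wavelength Photon wavelength, Angstrom. Must be > 0.
#' @param energy Photon energy, keV. Must be > 0.
#' @param two_theta Scattering angle 2*theta in degrees, in [0, 180).
#'
#' @return A numeric vector of the converted quantity.
#'
#' @examples
#' q_to_d(0.0295)                    # ~213 Angstrom repeat
#' wavelength_to_energy(1.0322)      # ~12.0 keV
#' two_theta_to_q(1, 1.5418)
#' @name saxs_units
NULL

# hc in keV * Angstrom
.hc_keV_A <- 12.3984

#' @rdname saxs_units
#' @export
q_to_d <- function(q) {
  if (any(!is.finite(q) | q <= 0)) {
    abort("`q` must be finite and > 0.", class = "lcp_domain_error")
  }
  2 * pi / q
}

#' @rdname saxs_units
#' @export
d_to_q <- function(d) {
  if (any(!is.finite(d) | d <= 0)) {
    abort("`d` must be finite and > 0.", class = "lcp_domain_error")
  }
  2 * pi / d
}

#' @rdname saxs_units
#' @export
wavelength_to_energy <- function(wavelength) {
  if (any(!is.finite(wavelength) | wavelength <= 0)) {
    abort("`wavelength` must be finite and > 0.", class = "lcp_domain_error")
  }
  .hc_keV_A / wavelength
}

#' @rdname saxs_units
#' @export
energy_to_wavelength <- function(energy) {
  if (any(!is.finite(energy) | energy <= 0)) {
    abort("`energy` must be finite and > 0.", class = "lcp_domain_error")
  }
  .hc_keV_A / energy
}

#' @rdname saxs_units
#' @export
two_theta_to_q <- function(two_theta, wavelength) {
  if (any(!is.finite(two_theta) | two_theta < 0 | two_theta >= 180)) {
    abort("`two_theta` must be in [0, 180) degrees.", class = "lcp_domain_error")
  }
  if (any(!is.finite(wavelength) | wavelength <= 0)) {
    abort("`wavelength` must be finite and > 0.", class = "lcp_domain_error")
  }
  (4 * pi / wavelength) * sin(two_theta / 2 * pi / 180)
}
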