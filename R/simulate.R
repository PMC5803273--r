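#' Simulate a 1-D powder SAXS profile of a lipid mesophase
#'
#' Generates a synthetic scattering curve with Bragg peaks at the allowed
#' reflection positions of the requested phase, a smooth power-law-plus-
#' constant background, and multiplicative Gaussian noise — the features of a
#' reduced synchrotron powder pattern that matter for position-based indexing.
#' Peak heights decay as `(m_i / m_1)^-intensity_decay`; exact structure
#' factors are irrelevant to indexing and are not modelled. The same seed
#' yields bit-identical output.
#'
#' @param phase Phase name (see [phase_models()]).
#' @param lattice Lattice parameter (cubic edge / lamellar repeat / hexagonal
#'   edge), Angstrom.
#' @param n_reflections Number of allowed reflections to place (capped at the
#'   model's list). Reflections falling beyond `q_max` contribute nothing but
#'   remain listed in the ground truth.
#' @param peak_shape `"lorentzian"` (default) or `"gaussian"`.
#' @param fwhm Full width at half maximum of each peak, 1/Angstrom.
#' @param intensity_decay Exponent p in the `m^-p` height decay (default 2).
#' @param background Named or positional numeric vector
#'   `c(amplitude, power, constant)` for `amplitude * q^-power + constant`.
#' @param noise_rel_sigma Relative standard deviation of the multiplicative
#'   Gaussian noise (0 disables noise).
#' @param q_min,q_max,n_points Uniform Q grid specification, 1/Angstrom.
#' @param seed Integer seed for the noise draw; `NULL` uses (and advances) the
#'   session RNG. The session RNG state is restored when a seed is given.
#' @param meta Metadata list stored on the profile.
#'
#' @return A list with elements `profile` (a [saxs_profile()]) and `truth`
#'   (list: `phase`, `lattice`, `q_centers`, `heights`, `multipliers`).
#' @export
#' @examples
#' sim <- simulate_saxs_profile("Ia3d", 525, seed = 7)
#' head(sim$truth$q_centers)
simulate_saxs_profile <- function(phase, lattice, n_reflections = 4,
                                  peak_shape = c("lorentzian", "gaussian"),
                                  fwhm = 0.002, intensity_decay = 2,
                                  background = c(amplitude = 1e-5, power = 2,
                                                 constant = 0.01),
                                  noise_rel_sigma = 0.01,
                                  q_min = 0.004, q_max = 0.5, n_points = 2000,
                                  seed = NULL, meta = list()) {
  peak_shape <- match.arg(peak_shape)
  if (lattice <= 0) abort("`lattice` must be > 0.", class = "lcp_domain_error")
  if (n_reflections < 2) {
    abort("`n_reflections` must be >= 2.", class = "lcp_spec_error")
  }
  model <- phase_models(phase)
  m <- model$multipliers[[1]]
  m <- m[seq_len(min(n_reflections, length(m)))]
  k <- .lattice_to_scale(lattice, model$family)
  centers <- k * m
  if (centers[1] < q_min || centers[2] > q_max) {
    abort(sprintf(
      "Q grid [%.4g, %.4g] must cover the first two reflections (%.4g, %.4g).",
      q_min, q_max, centers[1], centers[2]), class = "lcp_spec_error")
  }
  heights <- (m / m[1])^(-intensity_decay)

  q <- seq(q_min, q_max, length.out = n_points)
  signal <- .peak_signal(q, centers, heights, fwhm, peak_shape) +
    background[[1]] * q^(-background[[2]]) + background[[3]]
  intensity <- .with_seed(seed, {
    if (noise_rel_sigma > 0) {
      signal * (1 + noise_rel_sigma * stats::rnorm(length(signal)))
    } else signal
  })

  list(profile = saxs_profile(q, pmax(intensity, 0), meta = meta),
       truth = list(phase = model$phase, lattice = lattice,
                    q_centers = centers, heights = heights, multipliers = m))
}

.lattice_to_scale <- function(lattice, family) {
  switch(family,
    cubic = 2 * pi / lattice,
    lamellar = 2 * pi / lattice,
    hexagonal = 4 * pi / (sqrt(3) * lattice))
}

.peak_signal <- function(q, centers, heights, fwhm, shape) {
  sig <- numeric(length(q))
  for (i in seq_along(centers)) {
    if (shape == "lorentzian") {
      g <- fwhm / 2
      sig <- sig + heights[i] * g^2 / ((q - centers[i])^2 + g^2)
    } else {
      sig <- sig + heights[i] * exp(-4 * log(2) * (q - centers[i])^2 / fwhm^2)
    }
  }
  sig
}

# evaluate `expr` under a temporary RNG state when seed is given
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a two-phase coexistence pattern
#'
#' Weighted sum of the two phases' noiseless signals on a shared Q grid,
#' followed by a single multiplicative noise pass, so that `weight = 1`
#' reproduces [simulate_saxs_profile()] of the first phase exactly (same
#' seed) and the mixture is symmetric under swapping the phases at
#' `weight = 0.5`.
#'
#' @param spec_a,spec_b Named lists of arguments for the two components:
#'   `phase`, `lattice`, and optionally `n_reflections`, `peak_shape`,
#'   `fwhm`, `intensity_decay`.
#' @param weight Weight of component A in (0, 1].
#' @inheritParams simulate_saxs_profile
#' @return As [simulate_saxs_profile()]; `truth` lists both components.
#' @export
#' @examples
#' mix <- simulate_coexistence(list(phase = "Ia3d", lattice = 500),
#'                             list(phase = "La", lattice = 55),
#'                             weight = 0.7, noise_rel_sigma = 0, seed = 1)
simulate_coexistence <- function(spec_a, spec_b, weight = 0.5,
                                 background = c(amplitude = 1e-5, power = 2,
                                                constant = 0.01),
                                 noise_rel_sigma = 0.01,
                                 q_min = 0.004, q_max = 0.5, n_points = 2000,
                                 seed = NULL, meta = list()) {
  if (weight <= 0 || weight > 1) {
    abort("`weight` must be in (0, 1].", class = "lcp_spec_error")
  }
  sim1 <- function(spec) {
    do.call(simulate_saxs_profile,
            c(spec, list(background = c(0, 1, 0), noise_rel_sigma = 0,
                         q_min = q_min, q_max = q_max, n_points = n_points)))
  }
  a <- sim1(spec_a)
  b <- sim1(spec_b)
  signal <- weight * a$profile$intensity + (1 - weight) * b$profile$intensity +
    background[[1]] * a$profile$q^(-background[[2]]) + background[[3]]
  intensity <- .with_seed(seed, {
    if (noise_rel_sigma > 0) {
      signal * (1 + noise_rel_sigma * stats::rnorm(length(signal)))
    } else signal
  })
  list(profile = saxs_profile(a$profile$q, pmax(intensity, 0), meta = meta),
       truth = list(components = list(a$truth, b$truth), weight = weight))
}

#' Synthetic hydration series mirroring the studied phase sequences
#'
#' Builds a hydration series of simulated samples at a fixed phospholipid
#' level reproducing the experimentally observed phase sequences: at 5 wt%
#' DSPG of the lipid mix, Pn3m (55-60% w/w water) -> Im3m (65-75%) -> Pn3m
#' (80%); at 8 wt%, Ia3d (60%) -> Pn3m (65-70%) -> Ia3d (75-80%). The 80%
#' w/w lattice parameters are anchored at the measured endpoints (301 A Pn3m
#' for 5 wt%; 525 A Ia3d for 8 wt%); all intermediate lattice values are
#' synthetic linear interpolations in hydration, not measured values.
#'
#' @param dspg_wt_pct Phospholipid level, 5 or 8 (wt% of the lipid mix).
#' @param seed Integer seed; sample i uses `seed + i` for its noise draw.
#' @param noise_rel_sigma Relative noise level (default 0.01).
#' @param n_reflections Reflections per simulated pattern (default 4).
#' @return A tibble with one row per sample: `sample_id`, `water_wt_pct`,
#'   `dspg_wt_pct_of_lipid`, `lipid_density`, `water_density`,
#'   `phase_true`, `lattice_true`, and a `profile` list-column.
#' @export
#' @examples
#' series <- simulate_hydration_series(8, seed = 1)
#' series$phase_true
simulate_hydration_series <- function(dspg_wt_pct, seed = 1,
                                      noise_rel_sigma = 0.01,
                                      n_reflections = 4) {
  if (!dspg_wt_pct %in% c(5, 8)) {
    abort("`dspg_wt_pct` must be 5 or 8.", class = "lcp_spec_error")
  }
  if (dspg_wt_pct == 5) {
    water <- c(55, 60, 65, 70, 75, 80)
    phases <- c("Pn3m", "Pn3m", "Im3m", "Im3m", "Im3m", "Pn3m")
    lattice <- 150 + (301 - 150) * (water - 55) / 25
  } else {
    water <- c(60, 65, 70, 75, 80)
    phases <- c("Ia3d", "Pn3m", "Pn3m", "Ia3d", "Ia3d")
    lattice <- 180 + (525 - 180) * (water - 60) / 20
  }
  sims <- purrr::map(seq_along(water), function(i) {
    simulate_saxs_profile(
      phase = phases[i], lattice = lattice[i],
      n_reflections = n_reflections, noise_rel_sigma = noise_rel_sigma,
      seed = seed + i,
      meta = list(sample_id = sprintf("dspg%02d_w%02d", dspg_wt_pct, water[i]),
                  water_wt_pct = water[i]))
  })
  tibble::tibble(
    sample_id = sprintf("dspg%02d_w%02d", dspg_wt_pct, water),
    water_wt_pct = water,
    dspg_wt_pct_of_lipid = dspg_wt_pct,
    lipid_density = 0.982,
    water_density = 1.0,
    phase_true = phases,
    lattice_true = lattice,
    profile = purrr::map(sims, "profile")
  )
}
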