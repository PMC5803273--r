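#' Detect Bragg peaks in a 1-D SAXS profile
#'
#' Finds local maxima of the baseline-subtracted intensity, keeps those whose
#' prominence reaches `min_rel_prominence` times the global maximum of the
#' subtracted signal, enforces a minimum peak separation (higher-prominence
#' peaks win), and refines each surviving position by 3-point parabolic
#' interpolation around the grid maximum. Peak width (FWHM) is measured by
#' linear interpolation at half height on the subtracted signal. No peak-shape
#' model is fitted: indexing downstream needs positions, not shapes.
#'
#' Prominence follows the topographic convention: the drop from the peak to
#' the higher of the two key saddles separating it from taller terrain (or the
#' signal edge).
#'
#' @param profile Data frame with columns `q` and `intensity`.
#' @param min_rel_prominence Minimum prominence as a fraction of the global
#'   maximum of the baseline-subtracted signal. Default 0.02.
#' @param min_separation Minimum distance between peak centers, in 1/Angstrom.
#'   Default: 3 grid steps.
#' @param baseline_window Passed to [estimate_baseline()] (points).
#' @param max_peaks Keep at most this many peaks (highest prominence first).
#'   Default 12.
#' @param min_snr Noise guard: a peak's prominence must also exceed `min_snr`
#'   times the robust scatter (MAD) of the baseline-subtracted signal. The
#'   default 10 sits above the full prominence range pure Gaussian noise
#'   attains on grids of a few thousand points (about 7 sigma), so
#'   noise-only profiles yield no peaks while reflections at
#'   signal-to-noise >= 10 pass easily.
#'
#' @return A tibble with columns `q_center`, `height` (above baseline),
#'   `prominence`, `fwhm`, sorted by ascending `q_center`. Zero rows when no
#'   peak passes the thresholds.
#' @export
#' @examples
#' sim <- simulate_saxs_profile(phase = "Pn3m", lattice = 301,
#'                              n_reflections = 3, noise_rel_sigma = 0, seed = 1)
#' find_peaks(sim$profile)
find_peaks <- function(profile, min_rel_prominence = 0.02,
                       min_separation = NULL, baseline_window = NULL,
                       max_peaks = 12, min_snr = 10) {
  if (min_rel_prominence <= 0 || min_rel_prominence >= 1) {
    abort("`min_rel_prominence` must be in (0, 1).",
          class = "lcp_parameter_error")
  }
  q <- profile$q
  y <- profile$intensity - estimate_baseline(profile, window = baseline_window)
  n <- length(y)
  if (is.null(min_separation)) {
    min_separation <- 3 * stats::median(diff(q))
  }
  if (min_separation <= 0) {
    abort("`min_separation` must be > 0.", class = "lcp_parameter_error")
  }

  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  # plateaus: diff(sign(diff)) misses flat tops; acceptable on float data
  is_max <- is_max[y[is_max] > 0]
  if (length(is_max) == 0) return(.empty_peaks())

  prom <- vapply(is_max, .prominence, numeric(1), y = y)
  thr <- min_rel_prominence * max(y)
  noise_floor <- min_snr * stats::mad(y)
  keep <- prom >= thr & (noise_floor <= 0 | prom >= noise_floor)
  is_max <- is_max[keep]
  prom <- prom[keep]
  if (length(is_max) == 0) return(.empty_peaks())

  # separation: greedily accept in order of decreasing prominence
  ord <- order(prom, decreasing = TRUE)
  accepted <- integer(0)
  for (j in ord) {
    if (all(abs(q[is_max[j]] - q[is_max[accepted]]) >= min_separation)) {
      accepted <- c(accepted, j)
    }
  }
  accepted <- accepted[seq_len(min(length(accepted), max_peaks))]
  idx <- is_max[accepted]
  prom <- prom[accepted]

  centers <- vapply(idx, .parabolic_center, numeric(1), q = q, y = y)
  heights <- y[idx]
  fwhms <- vapply(idx, .fwhm_interp, numeric(1), q = q, y = y)

  out <- tibble::tibble(q_center = centers, height = heights,
                        prominence = prom, fwhm = fwhms)
  dplyr::arrange(out, .data$q_center)
}

.empty_peaks <- function() {
  tibble::tibble(q_center = numeric(0), height = numeric(0),
                 prominence = numeric(0), fwhm = numeric(0))
}

# topographic prominence of the local maximum at index i
.prominence <- function(i, y) {
  n <- length(y)
  left_min <- y[i]
  j <- i - 1L
  lbase <- min(y[seq_len(i)])
  while (j >= 1) {
    if (y[j] > y[i]) { lbase <- min(y[j:i]); break }
    j <- j - 1L
  }
  rbase <- min(y[i:n])
  j <- i + 1L
  while (j <= n) {
    if (y[j] > y[i]) { rbase <- min(y[i:j]); break }
    j <- j + 1L
  }
  y[i] - max(lbase, rbase)
}

# 3-point parabolic refinement of the peak position
.parabolic_center <- function(i, q, y) {
  n <- length(y)
  if (i <= 1 || i >= n) return(q[i])
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom >= 0) return(q[i])
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 0.5), -0.5)
  # local grid step (grids may be non-uniform)
  step <- if (delta >= 0) q[i + 1] - q[i] else q[i] - q[i - 1]
  q[i] + delta * step
}

# full width at half maximum by linear interpolation on the subtracted signal
.fwhm_interp <- function(i, q, y) {
  n <- length(y)
  half <- y[i] / 2
  jl <- i
  while (jl > 1 && y[jl] > half) jl <- jl - 1L
  ql <- if (y[jl] > half) q[jl] else {
    q[jl] + (q[jl + 1] - q[jl]) * (half - y[jl]) / (y[jl + 1] - y[jl])
  }
  jr <- i
  while (jr < n && y[jr] > half) jr <- jr + 1L
  qr <- if (y[jr] > half) q[jr] else {
    q[jr - 1] + (q[jr] - q[jr - 1]) * (y[jr - 1] - half) / (y[jr - 1] - y[jr])
  }
  qr - ql
}

#' Write detected peaks to CSV
#'
#' @param peaks Tibble from [find_peaks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE)
  invisible(path)
}
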