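#' Estimate a smooth baseline under a 1-D SAXS profile
#'
#' Computes a lower envelope of the scattering curve from rolling-minimum
#' anchor points followed by rolling-mean smoothing. A grid point is an anchor
#' when it attains the minimum of the one-sided rolling window ending or
#' starting at it; on smooth background regions (including steep power-law
#' upturns at low q) every point qualifies, so the envelope reproduces the
#' background exactly there, while points on peaks — which rise above the
#' background on the scale of the window — are excluded and bridged by linear
#' interpolation. A short rolling-mean pass then smooths the envelope; it is
#' kept short so curved backgrounds are not inflated.
#'
#' @param profile Data frame with columns `q` and `intensity`.
#' @param window Width of the rolling-minimum window in points; must exceed
#'   the widest peak. Default: 15% of the profile length (at least 3). Must be
#'   >= 3 and < the profile length.
#' @param smooth_window Width of the final rolling-mean pass; default
#'   `max(3, window %/% 30)`, clipped to odd.
#' @return Numeric vector, same length as the profile: the estimated baseline.
#' @export
#' @examples
#' prof <- simulate_saxs_profile(phase = "Pn3m", lattice = 150,
#'                               noise_rel_sigma = 0, seed = 1)$profile
#' b <- estimate_baseline(prof)
estimate_baseline <- function(profile, window = NULL, smooth_window = NULL) {
  q <- profile$q
  y <- profile$intensity
  n <- length(y)
  if (is.null(window)) window <- max(3, round(0.15 * n))
  if (window < 3 || window >= n) {
    abort("`window` must be >= 3 and smaller than the profile length.",
          class = "lcp_parameter_error")
  }
  h <- max(1L, window %/% 2)
  if (is.null(smooth_window)) smooth_window <- max(3, window %/% 30)
  smooth_window <- .make_odd(min(smooth_window, n - 1))

  # one-sided rolling minima: min over [i-h, i] and over [i, i+h]
  left_min <- .roll_onesided_min(y, h, "left")
  right_min <- .roll_onesided_min(y, h, "right")
  tol <- 1e-12 * max(abs(y), 0)
  anchor <- (y <= left_min + tol) | (y <= right_min + tol)
  anchor[c(1, n)] <- anchor[c(1, n)] |
    c(y[1] <= right_min[1] + tol, y[n] <= left_min[n] + tol)
  if (sum(anchor) < 2) anchor[c(1, n)] <- TRUE

  base <- stats::approx(q[anchor], y[anchor], xout = q, rule = 2)$y
  smoothed <- .roll_pad(base, smooth_window, mean)
  # replicate-padded means are slope-biased where the background is steep;
  # keep the exact envelope on the edge regions
  hs <- (smooth_window - 1) %/% 2
  if (hs > 0) {
    edge <- c(seq_len(hs), seq(n - hs + 1, n))
    smoothed[edge] <- base[edge]
  }
  smoothed
}

.make_odd <- function(w) if (w %% 2 == 0) w + 1 else w

# rolling statistic with edge replication so the output has full length
.roll_pad <- function(x, width, fn) {
  h <- (width - 1) %/% 2
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(zoo::rollapply(xp, width, fn, align = "center"))
}

# min over the window of h points ending at i ("left") or starting at i
# ("right"), edges using the available partial window
.roll_onesided_min <- function(x, h, side) {
  n <- length(x)
  if (side == "left") {
    xp <- c(rep(x[1], h), x)
    as.numeric(zoo::rollapply(xp, h + 1, min, align = "right"))
  } else {
    xp <- c(x, rep(x[n], h))
    as.numeric(zoo::rollapply(xp, h + 1, min, align = "left"))
  }
}
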