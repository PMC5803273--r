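#' Index peaks against a single mesophase reflection series
#'
#' Assigns detected Bragg peaks to the allowed reflection positions
#' `q_i = k * m_i` of one phase and fits the scale `k` (hence the lattice
#' parameter) by height-weighted least squares, minimizing
#' `sum(w_i * (q_i - k * m_i)^2)`.
#'
#' Because first-order reflections of ultra-swollen lattices can be lost in
#' the beamstop, the lowest-q peak is anchored to each of the first three
#' allowed multipliers in turn. For each anchoring the remaining peaks are
#' greedily matched, in ascending order, to the nearest unused higher
#' multiplier whose predicted position lies within `rel_tol` (relative), the
#' scale being refit after every accepted match. The anchoring with the best
#' score wins (ties: more matched peaks, then lower rms); the fit is flagged
#' unfitted when fewer than 2 peaks match. Reflection-ratio degeneracies are
#' real — a lamellar 1:2 pair scales exactly onto sqrt(2):sqrt(8), and a
#' series starting at sqrt(3) onto one starting at sqrt(4) — so patterns made
#' only of high-order reflections with gaps can index to a rescaled lattice;
#' the skip penalty resolves every degeneracy in which the true assignment
#' uses lower orders.
#'
#' The score is `n_matched - 4 * rms_rel_residual / rel_tol - 0.5 * n_skipped`,
#' where `n_skipped` counts allowed multipliers below the highest matched one
#' that were left unmatched. The skip penalty is what separates phases whose
#' reflection ratios are subsets of another's (an Im3m series also matches
#' Pn3m multipliers, but only by skipping Pn3m's sqrt(3)).
#'
#' @param peaks Data frame with column `q_center` (1/Angstrom) and optionally
#'   `height` (weights; default 1).
#' @param phase Phase name (see [phase_models()]) or a one-row phase model.
#' @param rel_tol Relative matching tolerance, in (0, 0.05). Default 0.005.
#' @return An object of class `lcp_fit`: a list with elements `phase`,
#'   `family`, `fitted`, `lattice` (Angstrom), `k`, `matches` (tibble:
#'   `peak`, `q_obs`, `multiplier`, `q_pred`, `rel_residual`), `n_matched`,
#'   `rms_rel_residual`, `n_skipped`, `score`, `rel_tol`.
#' @seealso [rank_phases()], [decompose_coexistence()]
#' @export
#' @examples
#' pk <- tibble::tibble(q_center = 2 * pi * sqrt(c(2, 3, 4)) / 100, height = 1)
#' index_phase(pk, "Pn3m")
index_phase <- function(peaks, phase, rel_tol = 0.005) {
  if (rel_tol <= 0 || rel_tol >= 0.05) {
    abort("`rel_tol` must be in (0, 0.05).", class = "lcp_parameter_error")
  }
  model <- if (is.character(phase)) phase_models(phase) else phase
  m <- model$multipliers[[1]]
  q <- peaks$q_center
  w <- if ("height" %in% names(peaks)) peaks$height else rep(1, length(q))
  ord <- order(q)
  q <- q[ord]; w <- w[ord]

  nofit <- structure(list(phase = model$phase, family = model$family,
                          fitted = FALSE, lattice = NA_real_, k = NA_real_,
                          matches = NULL, n_matched = 0L,
                          rms_rel_residual = NA_real_, n_skipped = NA_integer_,
                          score = -Inf, rel_tol = rel_tol),
                     class = "lcp_fit")
  if (length(q) < 2) return(nofit)

  best <- nofit
  for (anchor in seq_len(min(3, length(m)))) {
    cand <- .greedy_match(q, w, m, anchor, rel_tol)
    if (is.null(cand)) next
    better <- cand$score > best$score ||
      (cand$score == best$score && length(cand$pk_idx) > best$n_matched) ||
      (cand$score == best$score && length(cand$pk_idx) == best$n_matched &&
         isTRUE(cand$rms < best$rms_rel_residual))
    if (better) best <- .as_lcp_fit(cand, model, q, rel_tol)
  }
  best
}

# one anchoring pass; returns NULL when fewer than 2 peaks match
.greedy_match <- function(q, w, m, anchor, rel_tol) {
  k <- q[1] / m[anchor]
  pk_idx <- 1L
  mult_idx <- anchor
  for (i in seq_along(q)[-1]) {
    avail <- setdiff(seq_along(m), mult_idx)
    avail <- avail[avail > max(mult_idx)]
    if (length(avail) == 0) break
    pred <- k * m[avail]
    rel <- abs(q[i] - pred) / pred
    j <- which.min(rel)
    if (rel[j] <= rel_tol) {
      pk_idx <- c(pk_idx, i)
      mult_idx <- c(mult_idx, avail[j])
      k <- sum(w[pk_idx] * q[pk_idx] * m[mult_idx]) /
           sum(w[pk_idx] * m[mult_idx]^2)
    }
  }
  if (length(pk_idx) < 2) return(NULL)
  rel_res <- (q[pk_idx] - k * m[mult_idx]) / (k * m[mult_idx])
  rms <- sqrt(mean(rel_res^2))
  n_skipped <- max(mult_idx) - length(mult_idx)
  score <- length(pk_idx) - 4 * rms / rel_tol - 0.5 * n_skipped
  list(k = k, pk_idx = pk_idx, mult_idx = mult_idx, rel_res = rel_res,
       rms = rms, n_skipped = n_skipped, score = score)
}

.as_lcp_fit <- function(cand, model, q, rel_tol) {
  m <- model$multipliers[[1]]
  structure(list(
    phase = model$phase, family = model$family, fitted = TRUE,
    lattice = scale_to_lattice(cand$k, model$family), k = cand$k,
    matches = tibble::tibble(
      peak = cand$pk_idx, q_obs = q[cand$pk_idx],
      multiplier = m[cand$mult_idx], q_pred = cand$k * m[cand$mult_idx],
      rel_residual = cand$rel_res),
    n_matched = length(cand$pk_idx), rms_rel_residual = cand$rms,
    n_skipped = as.integer(cand$n_skipped), score = cand$score,
    rel_tol = rel_tol), class = "lcp_fit")
}

#' @export
print.lcp_fit <- function(x, ...) {
  if (!x$fitted) {
    cat(sprintf("<lcp_fit> %s: no fit\n", x$phase))
    return(invisible(x))
  }
  unit <- if (x$family == "lamellar") "d" else "a"
  cat(sprintf("<lcp_fit> %s: %s = %.2f A, %d reflections, rms %.2e, score %.2f\n",
              x$phase, unit, x$lattice, x$n_matched, x$rms_rel_residual,
              x$score))
  invisible(x)
}

#' @describeIn index_phase One row per matched reflection.
#' @param x,... An `lcp_fit` object; unused extra arguments.
#' @method tidy lcp_fit
#' @export
tidy.lcp_fit <- function(x, ...) {
  if (!x$fitted) return(tibble::tibble())
  x$matches
}

#' @describeIn index_phase One-row model summary
#'   (`phase`, `family`, `fitted`, `lattice`, `n_matched`,
#'   `rms_rel_residual`, `n_skipped`, `score`).
#' @method glance lcp_fit
#' @export
glance.lcp_fit <- function(x, ...) {
  tibble::tibble(phase = x$phase, family = x$family, fitted = x$fitted,
                 lattice = x$lattice, n_matched = x$n_matched,
                 rms_rel_residual = x$rms_rel_residual,
                 n_skipped = x$n_skipped, score = x$score)
}

#' Rank candidate phases for a set of peaks
#'
#' Runs [index_phase()] for every candidate and returns the successful fits
#' sorted by decreasing score (ties broken by lower rms residual, then by
#' phase name for a fully deterministic ordering).
#'
#' @inheritParams index_phase
#' @param candidates Phase model tibble (see [phase_models()]) or character
#'   vector of phase names. Default: Ia3d, Pn3m, Im3m, La.
#' @return A tibble with one row per fitted candidate: the [glance()] columns
#'   plus `matched_intensity` (sum of matched peak heights) and a `fit`
#'   list-column holding the `lcp_fit` objects. Zero rows if nothing fits.
#' @export
#' @examples
#' pk <- tibble::tibble(q_center = 2 * pi * sqrt(c(2, 3, 4, 6)) / 200, height = 1)
#' rank_phases(pk)
rank_phases <- function(peaks, candidates = phase_models(), rel_tol = 0.005) {
  if (is.character(candidates)) candidates <- phase_models(candidates)
  fits <- lapply(seq_len(nrow(candidates)),
                 function(i) index_phase(peaks, candidates[i, ], rel_tol))
  fits <- fits[vapply(fits, function(f) f$fitted, logical(1))]
  if (length(fits) == 0) {
    return(tibble::tibble(phase = character(0), family = character(0),
                          fitted = logical(0), lattice = numeric(0),
                          n_matched = integer(0), rms_rel_residual = numeric(0),
                          n_skipped = integer(0), score = numeric(0),
                          matched_intensity = numeric(0), fit = list()))
  }
  w <- if ("height" %in% names(peaks)) peaks$height else rep(1, nrow(peaks))
  q_sorted_w <- w[order(peaks$q_center)]
  tab <- dplyr::bind_rows(lapply(fits, glance))
  tab$matched_intensity <- vapply(
    fits, function(f) sum(q_sorted_w[f$matches$peak]), numeric(1))
  tab$fit <- fits
  dplyr::arrange(tab, dplyr::desc(.data$score), .data$rms_rel_residual,
                 .data$phase)
}

#' Decompose a possibly two-phase pattern by greedy peeling
#'
#' Fits the best-ranking phase, removes its matched peaks, and re-runs the
#' ranking on the remainder. A second phase is reported only when it matches
#' at least 2 of the residual peaks. Results are ordered by total matched
#' intensity so the majority phase comes first.
#'
#' @inheritParams rank_phases
#' @param max_phases Maximum number of coexisting phases to report (default 2).
#' @return A tibble in the format of [rank_phases()] with at most `max_phases`
#'   rows, ordered by decreasing matched intensity.
#' @export
decompose_coexistence <- function(peaks, candidates = phase_models(),
                                  rel_tol = 0.005, max_phases = 2) {
  if (is.character(candidates)) candidates <- phase_models(candidates)
  remaining <- dplyr::arrange(tibble::as_tibble(peaks), .data$q_center)
  if (!"height" %in% names(remaining)) remaining$height <- 1
  out <- list()
  for (round in seq_len(max_phases)) {
    if (nrow(remaining) < 2) break
    ranked <- rank_phases(remaining, candidates, rel_tol)
    if (nrow(ranked) == 0) break
    top <- ranked[1, ]
    out[[round]] <- top
    remaining <- remaining[-top$fit[[1]]$matches$peak, , drop = FALSE]
  }
  if (length(out) == 0) {
    return(rank_phases(remaining[0, ], candidates, rel_tol))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, dplyr::desc(.data$matched_intensity))
}
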