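#' Assemble a hydration-resolved phase diagram from profiles
#'
#' Runs the full per-sample analysis — baseline + peak detection, phase
#' indexing with coexistence peeling, and (for cubic assignments)
#' water-channel geometry — over a table of samples, producing one diagram
#' point per sample with full provenance. Samples where nothing indexes are
#' retained and flagged, never dropped.
#'
#' @param samples Tibble with one row per sample. Required columns:
#'   `sample_id`, `water_wt_pct`, `dspg_wt_pct_of_lipid`, and `profile`
#'   (list-column of data frames with `q`, `intensity`). Optional:
#'   `lipid_density` (default 0.982), `water_density` (default 1.0).
#' @param candidates Phase models to try (default [phase_models()]).
#' @param rel_tol Indexing tolerance (default 0.005).
#' @param min_rel_prominence,max_peaks Peak-detection settings
#'   (see [find_peaks()]).
#' @param max_phases Maximum coexisting phases per sample (default 2).
#'
#' @return A tibble with one row per sample: the identifying columns, the
#'   dominant assignment (`phase`, `lattice`, `n_matched`, `rms_rel_residual`,
#'   `score`), `n_assignments`, `unassigned`, channel geometry columns
#'   (`phi`, `l`, `r`, `d_w`; NA when the dominant assignment is lamellar or
#'   the point is unassigned), plus list-columns `assignments` (the
#'   [decompose_coexistence()] table, geometry columns filled per cubic
#'   assignment) and `peaks`.
#' @export
#' @examples
#' series <- simulate_hydration_series(8, seed = 1)
#' diagram <- build_diagram(series)
#' diagram[, c("sample_id", "phase", "lattice", "d_w")]
build_diagram <- function(samples, candidates = phase_models(),
                          rel_tol = 0.005, min_rel_prominence = 0.02,
                          max_peaks = 12, max_phases = 2) {
  if (!is.data.frame(samples) || nrow(samples) == 0) {
    abort("`samples` must be a data frame with at least one row.",
          class = "lcp_validation_error")
  }
  need <- c("sample_id", "water_wt_pct", "dspg_wt_pct_of_lipid", "profile")
  missing <- setdiff(need, names(samples))
  if (length(missing) > 0) {
    abort(paste0("`samples` lacks column(s): ", paste(missing, collapse = ", ")),
          class = "lcp_validation_error")
  }
  samples <- tibble::as_tibble(samples)
  if (!"lipid_density" %in% names(samples)) samples$lipid_density <- 0.982
  if (!"water_density" %in% names(samples)) samples$water_density <- 1.0

  rows <- purrr::map(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    peaks <- find_peaks(s$profile[[1]],
                        min_rel_prominence = min_rel_prominence,
                        max_peaks = max_peaks)
    assignments <- decompose_coexistence(peaks, candidates, rel_tol,
                                         max_phases = max_phases)
    unassigned <- nrow(assignments) == 0
    comp <- composition(water_wt_frac = s$water_wt_pct / 100,
                        dspg_wt_frac_of_lipid = s$dspg_wt_pct_of_lipid / 100,
                        lipid_density = s$lipid_density,
                        water_density = s$water_density)
    # channel geometry for every cubic assignment (coexisting ones included)
    if (nrow(assignments) > 0) {
      geoms <- purrr::map(seq_len(nrow(assignments)), function(j) {
        if (assignments$phase[j] %in% cubic_phase_constants()$phase) {
          tryCatch(channel_geometry(assignments$lattice[j], comp,
                                    assignments$phase[j])[, c("phi", "l", "r",
                                                              "d_w")],
                   error = function(e) NULL)
        } else NULL
      })
      empty <- tibble::tibble(phi = NA_real_, l = NA_real_, r = NA_real_,
                              d_w = NA_real_)
      assignments <- dplyr::bind_cols(
        assignments,
        dplyr::bind_rows(purrr::map(geoms, function(g)
          if (is.null(g)) empty else g)))
    }
    if (unassigned) {
      dom <- tibble::tibble(phase = NA_character_, lattice = NA_real_,
                            n_matched = NA_integer_,
                            rms_rel_residual = NA_real_, score = NA_real_)
    } else {
      dom <- assignments[which.max(assignments$score),
                         c("phase", "lattice", "n_matched",
                           "rms_rel_residual", "score")]
    }
    geom <- if (unassigned) {
      tibble::tibble(phi = NA_real_, l = NA_real_, r = NA_real_, d_w = NA_real_)
    } else {
      # geometry of the dominant assignment (NA when it is not cubic)
      assignments[which.max(assignments$score), c("phi", "l", "r", "d_w")]
    }
    dplyr::bind_cols(
      s[, intersect(c("sample_id", "water_wt_pct", "dspg_wt_pct_of_lipid",
                      "lipid_density", "water_density"), names(s))],
      dom, geom,
      tibble::tibble(n_assignments = nrow(assignments),
                     unassigned = unassigned,
                     assignments = list(assignments), peaks = list(peaks)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lcp_diagram", class(out))
  out
}

#' Collapse a hydration series into phase runs
#'
#' Orders the diagram points of one phospholipid level by hydration, takes the
#' dominant phase at each point, and merges adjacent equal phases into runs.
#' Phase-boundary hydrations are reported as the midpoint between the adjacent
#' samples of different phase and are interval-censored: the true boundary
#' lies between the bracketing measured hydrations.
#'
#' @param points A [build_diagram()] result (or compatible data frame with
#'   `water_wt_pct`, `phase`, `dspg_wt_pct_of_lipid` columns) for a single
#'   phospholipid level.
#' @return An object of class `lcp_phase_sequence`: list with `dspg_wt_pct`,
#'   `steps` (tibble: `water_wt_pct`, `phase`), `runs` (tibble: `run`,
#'   `phase`, `water_min`, `water_max`, `n_points`), and `boundaries`
#'   (tibble: `from_phase`, `to_phase`, `water_lo`, `water_hi`, `midpoint`).
#' @export
#' @examples
#' diagram <- build_diagram(simulate_hydration_series(5, seed = 1))
#' collapse_sequence(diagram)
collapse_sequence <- function(points) {
  if (length(unique(points$dspg_wt_pct_of_lipid)) != 1) {
    abort("`points` must all share one phospholipid level.",
          class = "lcp_validation_error")
  }
  points <- dplyr::arrange(tibble::as_tibble(points), .data$water_wt_pct)
  if (any(duplicated(points$water_wt_pct))) {
    abort("Duplicate hydration values in the series.",
          class = "lcp_validation_error")
  }
  steps <- tibble::tibble(water_wt_pct = points$water_wt_pct,
                          phase = points$phase)
  ph <- ifelse(is.na(steps$phase), "unassigned", steps$phase)
  run_id <- cumsum(c(1L, as.integer(ph[-1] != ph[-length(ph)])))
  runs <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(run = run_id, phase = ph,
                                   water = steps$water_wt_pct), .data$run),
    phase = .data$phase[1],
    water_min = min(.data$water), water_max = max(.data$water),
    n_points = dplyr::n(), .groups = "drop")
  n_runs <- nrow(runs)
  boundaries <- if (n_runs > 1) {
    tibble::tibble(
      from_phase = runs$phase[-n_runs],
      to_phase = runs$phase[-1],
      water_lo = runs$water_max[-n_runs],
      water_hi = runs$water_min[-1],
      midpoint = (runs$water_max[-n_runs] + runs$water_min[-1]) / 2)
  } else {
    tibble::tibble(from_phase = character(0), to_phase = character(0),
                   water_lo = numeric(0), water_hi = numeric(0),
                   midpoint = numeric(0))
  }
  structure(list(dspg_wt_pct = points$dspg_wt_pct_of_lipid[1],
                 steps = steps, runs = runs, boundaries = boundaries),
            class = "lcp_phase_sequence")
}

#' @export
print.lcp_phase_sequence <- function(x, ...) {
  cat(sprintf("<lcp_phase_sequence> %g wt%% phospholipid: %s\n",
              x$dspg_wt_pct, paste(x$runs$phase, collapse = " -> ")))
  invisible(x)
}

#' Detect re-entrant phase behavior in a collapsed sequence
#'
#' A phase is re-entrant along the hydration axis when it occurs in two or
#' more non-adjacent runs of the collapsed sequence — it disappears and later
#' reappears as hydration increases.
#'
#' @param seq An `lcp_phase_sequence` from [collapse_sequence()], or a
#'   character vector of collapsed run labels.
#' @return One-row tibble: `collapsed` (run labels joined by " -> "),
#'   `n_runs`, `is_reentrant`, `reentrant_phase` (earliest recurring phase,
#'   NA when none).
#' @export
#' @examples
#' detect_reentrance(c("Pn3m", "Im3m", "Pn3m"))
detect_reentrance <- function(seq) {
  runs <- if (inherits(seq, "lcp_phase_sequence")) seq$runs$phase else seq
  if (length(runs) == 0) {
    abort("Empty phase sequence.", class = "lcp_validation_error")
  }
  # collapse defensively so the detector is idempotent on raw step lists
  runs <- runs[c(TRUE, runs[-1] != runs[-length(runs)])]
  considered <- runs[runs != "unassigned" & !is.na(runs)]
  recurring <- unique(considered[duplicated(considered)])
  first_pos <- if (length(recurring) > 0) {
    recurring[which.min(match(recurring, considered))]
  } else NA_character_
  tibble::tibble(collapsed = paste(runs, collapse = " -> "),
                 n_runs = length(runs),
                 is_reentrant = length(recurring) > 0,
                 reentrant_phase = first_pos)
}

#' Water-channel diameter as a function of hydration
#'
#' Extracts the tidy (hydration, phase, channel diameter) table from a
#' diagram, keeping only points with a cubic assignment and a valid channel
#' geometry; lamellar and unassigned points are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param points A [build_diagram()] result.
#' @return Tibble with columns `sample_id`, `water_wt_pct`,
#'   `dspg_wt_pct_of_lipid`, `phase`, `lattice` (`a`, Angstrom) and `d_w`
#'   (Angstrom), sorted by hydration; attribute `n_excluded` gives the number
#'   of omitted points.
#' @export
#' @examples
#' diagram <- build_diagram(simulate_hydration_series(8, seed = 1))
#' channel_vs_hydration(diagram)
channel_vs_hydration <- function(points) {
  points <- tibble::as_tibble(points)
  keep <- !is.na(points$d_w)
  out <- points[keep, c("sample_id", "water_wt_pct", "dspg_wt_pct_of_lipid",
                        "phase", "lattice", "d_w")]
  out <- dplyr::arrange(out, .data$water_wt_pct)
  attr(out, "n_excluded") <- sum(!keep)
  out
}
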