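#' Construct a SAXS profile tibble
#'
#' A SAXS profile is a tibble with numeric columns `q` (scattering vector,
#' 1/Angstrom, strictly increasing, all > 0) and `intensity` (arbitrary
#' units, non-negative), carrying optional sample metadata as an attribute.
#' All profile-consuming functions in the package accept any data frame with
#' these two columns; this constructor validates and sorts.
#'
#' @param q Numeric vector of scattering-vector magnitudes (1/Angstrom).
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `q`.
#' @param meta Optional named list of sample metadata (sample id, temperature,
#'   composition reference, ...).
#'
#' @return A tibble of class `saxs_profile` with columns `q` and `intensity`,
#'   sorted by `q`.
#' @export
#' @examples
#' saxs_profile(seq(0.01, 0.1, length.out = 10), rep(1, 10))
saxs_profile <- function(q, intensity, meta = list()) {
  if (length(q) != length(intensity)) {
    abort("`q` and `intensity` must have the same length.",
          class = "lcp_validation_error")
  }
  keep <- is.finite(q) & is.finite(intensity)
  q <- as.numeric(q[keep])
  intensity <- as.numeric(intensity[keep])
  if (length(q) < 8) {
    abort("A SAXS profile needs at least 8 usable (finite) rows.",
          class = "lcp_insufficient_data")
  }
  if (any(q <= 0)) {
    abort("All `q` values must be > 0.", class = "lcp_validation_error")
  }
  ord <- order(q)
  q <- q[ord]
  intensity <- intensity[ord]
  if (any(diff(q) == 0)) {
    abort("`q` values must be distinct.", class = "lcp_validation_error")
  }
  out <- tibble::tibble(q = q, intensity = intensity)
  attr(out, "meta") <- meta
  class(out) <- c("saxs_profile", class(out))
  out
}

#' Read a 1-D SAXS profile from a two-column text file
#'
#' Accepts the common exports of detector-reduction software: whitespace- or
#' comma-separated numeric columns, `#` comment lines, and an optional header
#' row (auto-detected by a non-numeric first token). Rows with non-finite
#' values are dropped and the profile is sorted by `q`.
#'
#' @param path Path to the text file.
#' @param q_unit Unit of the first column: `"A^-1"` (default) or `"nm^-1"`
#'   (converted to 1/Angstrom by dividing by 10).
#' @param columns Length-2 integer vector giving the (q, intensity) column
#'   positions. Default `c(1, 2)`.
#' @param meta Optional metadata list attached to the profile.
#'
#' @return A [saxs_profile()] tibble.
#' @export
read_saxs_profile <- function(path, q_unit = c("A^-1", "nm^-1"),
                              columns = c(1, 2), meta = list()) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "lcp_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- seq_along(keep)[keep]
  if (length(lines) == 0) {
    abort(paste0("No data lines in ", path), class = "lcp_parse_error")
  }
  split_fields <- function(x) {
    strsplit(trimws(x), "[,;[:space:]]+")[[1]]
  }
  first <- split_fields(lines[[1]])
  has_header <- suppressWarnings(is.na(as.numeric(first[[1]])))
  if (has_header) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (length(lines) == 0) {
    abort(paste0("No data lines after header in ", path),
          class = "lcp_parse_error")
  }
  rows <- lapply(lines, split_fields)
  ncols <- vapply(rows, length, integer(1))
  need <- max(columns)
  bad <- which(ncols < need)
  if (length(bad) > 0) {
    abort(sprintf("Malformed line %d in %s: expected >= %d columns, found %d.",
                  lineno[bad[1]], path, need, ncols[bad[1]]),
          class = "lcp_parse_error")
  }
  qs <- suppressWarnings(vapply(rows, function(r) as.numeric(r[[columns[1]]]),
                                numeric(1)))
  is <- suppressWarnings(vapply(rows, function(r) as.numeric(r[[columns[2]]]),
                                numeric(1)))
  # a token that is neither numeric nor a missing-value literal is malformed
  # (literal NaN/NA/Inf rows are dropped later as non-finite)
  missing_literal <- function(tok) grepl("^-?(nan|na|inf)$", tolower(tok))
  for (col in 1:2) {
    vals <- if (col == 1) qs else is
    bad <- which(is.na(vals) & !vapply(rows, function(r)
      missing_literal(r[[columns[col]]]), logical(1)))
    if (length(bad) > 0) {
      abort(sprintf("Malformed line %d in %s: non-numeric value '%s'.",
                    lineno[bad[1]], path, rows[[bad[1]]][[columns[col]]]),
            class = "lcp_parse_error")
    }
  }
  if (q_unit == "nm^-1") qs <- qs / 10
  saxs_profile(qs, is, meta = meta)
}

#' Write a SAXS profile to a two-column text file
#'
#' @param profile Data frame with columns `q` and `intensity`.
#' @param path Output file path.
#' @param digits Significant digits written (default 12, lossless for
#'   round-tripping at the 1e-9 level).
#' @return `path`, invisibly.
#' @export
write_saxs_profile <- function(profile, path, digits = 12) {
  stopifnot(all(c("q", "intensity") %in% names(profile)))
  lines <- c("# q_A^-1 intensity",
             sprintf(paste0("%.", digits, "g %.", digits, "g"),
                     profile$q, profile$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample composition table
#'
#' Reads a CSV with one row per mesophase sample. Required columns:
#' `sample_id`, `dspg_wt_pct_of_lipid` (phospholipid as percent of the lipid
#' mix), `water_wt_pct` (water as percent of total sample mass). Optional:
#' `lipid_density_g_cm3` (default 0.982) and `water_density_g_cm3`
#' (default 1.0).
#'
#' @param path CSV file path.
#' @return A tibble with the columns above, defaults filled in.
#' @export
read_composition_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "lcp_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "dspg_wt_pct_of_lipid", "water_wt_pct")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("Composition table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lcp_validation_error")
  }
  if (is.null(df$lipid_density_g_cm3)) {
    df$lipid_density_g_cm3 <- rep(0.982, nrow(df))
  }
  if (is.null(df$water_density_g_cm3)) {
    df$water_density_g_cm3 <- rep(1.0, nrow(df))
  }
  if (any(df$water_wt_pct < 0 | df$water_wt_pct > 100)) {
    abort("water_wt_pct must lie in [0, 100].", class = "lcp_validation_error")
  }
  tibble::as_tibble(df)
}
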