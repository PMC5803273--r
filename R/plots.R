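#' Plot a SAXS profile
#'
#' Log-intensity scattering curve; detected peaks, when supplied, are marked
#' at their refined centers.
#'
#' @param object A [saxs_profile()] (or data frame with `q`, `intensity`).
#' @param peaks Optional [find_peaks()] table to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saxs_profile
#' @export
autoplot.saxs_profile <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ (ring(A)^-1)),
                  y = "Intensity (a.u., log scale)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$q_center),
                                 linetype = "dashed", colour = "firebrick",
                                 linewidth = 0.3)
  }
  p
}

#' Plot a phase diagram along the hydration axis
#'
#' One tile per sample, coloured by the dominant phase, faceted by
#' phospholipid level when several are present.
#'
#' @param diagram A [build_diagram()] result.
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(diagram) {
  df <- tibble::as_tibble(diagram)
  df$phase <- ifelse(is.na(df$phase), "unassigned", df$phase)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$water_wt_pct,
                                   y = factor(.data$dspg_wt_pct_of_lipid),
                                   fill = .data$phase)) +
    ggplot2::geom_tile(colour = "white", height = 0.8) +
    ggplot2::labs(x = "Water content (% w/w)",
                  y = "Phospholipid (wt% of lipid)", fill = "Phase") +
    ggplot2::theme_minimal()
}

#' Plot water-channel diameter versus hydration
#'
#' @param diagram A [build_diagram()] result (cubic points only are shown).
#' @return A ggplot object.
#' @export
plot_channel_vs_hydration <- function(diagram) {
  tab <- channel_vs_hydration(diagram)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$water_wt_pct, y = .data$d_w,
                                    colour = .data$phase,
                                    group = .data$phase)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Water content (% w/w)",
                  y = expression("Water channel diameter" ~ (ring(A))),
                  colour = "Phase") +
    ggplot2::theme_minimal()
}
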