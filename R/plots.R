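#' Histogram of smoothed indicine-origin probabilities by group
#'
#' The classic diagnostic for local-ancestry classification: pure taurine
#' animals should pile up near 0, pure indicine near 1, and composites show
#' both modes with mass split according to their admixture proportion.
#'
#' @param origins Output of [segment_origins()].
#' @param grouping Named character: group per animal id.
#' @param bins Histogram bins (default 40).
#' @return A ggplot object.
#' @export
plot_b_distribution <- function(origins, grouping, bins = 40) {
  dat <- dplyr::mutate(origins, group = unname(grouping[animal_id]))
  ggplot2::ggplot(dat, ggplot2::aes(x = smoothed_b)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "smoothed probability of indicine origin (b)",
                  y = "segment-haplotype count") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a scan result
#'
#' @param results Scan tibble with `chrom`, `pos_bp` and a p-value column.
#' @param p_col P-value column to plot (default `p_value`; `joint_p` for
#'   interaction scans).
#' @param threshold Reference significance line (default 1e-4).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, p_col = "p_value", threshold = 1e-4) {
  dat <- results[!is.na(results[[p_col]]), ]
  dat$logp <- -log10(dat[[p_col]])
  ggplot2::ggplot(dat, ggplot2::aes(x = pos_bp / 1e6, y = logp)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2,
                        colour = "red") +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Signed standardized effect versus implicated-allele frequency
#'
#' Scatter of estimate/SE against the within-subspecies frequency of the
#' allele inferred to track the mutant QTL allele, split by subspecies.
#'
#' @param plot_table Output of [effect_frequency_plot_table()].
#' @return A ggplot object.
#' @export
plot_effect_frequency <- function(plot_table) {
  ggplot2::ggplot(plot_table,
                  ggplot2::aes(x = frequency, y = signed_t,
                               colour = subspecies)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "allele frequency within subspecies",
                  y = "signed standardized effect (estimate / SE)") +
    ggplot2::theme_minimal()
}
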