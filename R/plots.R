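#' Bar chart of the nucleotide pile-up at one site
#'
#' The per-site view used to eyeball a candidate variant: counts of each
#' observed base (plus deletion-spanning reads) at a single reference
#' position.
#'
#' @param pileup A `pileup` object.
#' @param reference_name Reference name.
#' @param position 1-based position.
#' @return A ggplot object.
#' @export
plot_pileup_site <- function(pileup, reference_name, position) {
  site <- pileup_at(pileup, reference_name, position)
  long <- tidyr::pivot_longer(site, cols = c("A", "C", "G", "T", "N", "del"),
                              names_to = "base", values_to = "count")
  long$base <- factor(long$base, levels = c("A", "C", "G", "T", "N", "del"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$base, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      title = paste0(reference_name, ":", position,
                     " (depth ", site$depth, ")"),
      x = NULL, y = "reads") +
    ggplot2::theme_minimal()
}

#' Mapping rate across error allowances
#'
#' Line plot of mapping rate versus allowance, the standard robustness
#' picture for an allowance sweep.
#'
#' @param sweep Tibble with columns `allowance` and `mapping_rate` (e.g.
#'   built by mapping the same reads at several allowances and binding the
#'   [glance.seedmap_records()] rows).
#' @return A ggplot object.
#' @export
plot_allowance_sweep <- function(sweep) {
  stopifnot(all(c("allowance", "mapping_rate") %in% names(sweep)))
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$allowance,
                               y = .data$mapping_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "error allowance", y = "mapping rate") +
    ggplot2::theme_minimal()
}

#' Scatter of two quantifications on the log scale
#'
#' @param table_a,table_b Expression tibbles from [quantify_expression()].
#' @param pseudo Pseudo-count added before the log.
#' @return A ggplot object.
#' @export
plot_quant_comparison <- function(table_a, table_b, pseudo = 0.01) {
  j <- dplyr::inner_join(table_a, table_b, by = "transcript_id",
                         suffix = c("_a", "_b"))
  r <- quant_correlation(table_a, table_b, pseudo = pseudo)$r
  ggplot2::ggplot(j, ggplot2::aes(x = log10(.data$rpkm_a + pseudo),
                                  y = log10(.data$rpkm_b + pseudo))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "log10(RPKM + pseudo), run A",
                  y = "log10(RPKM + pseudo), run B",
                  subtitle = sprintf("Pearson r = %.4f (log scale)", r)) +
    ggplot2::theme_minimal()
}
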