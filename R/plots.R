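#' Manhattan plot of per-SNP FST
#'
#' Genome-position scatter of per-SNP FST with the outlier quantile marked.
#' For large SNP sets pass `thin` to plot every `thin`-th SNP.
#'
#' @param fst Per-SNP FST tibble from [snp_fst()].
#' @param q Quantile to mark (default 0.999).
#' @param thin Keep every `thin`-th SNP (default 1, no thinning).
#' @return A ggplot.
#' @export
plot_manhattan <- function(fst, q = 0.999, thin = 1L) {
  thr <- quantile_threshold(fst$fst, q)
  dat <- fst |>
    dplyr::filter(!is.na(.data$fst)) |>
    dplyr::filter(dplyr::row_number() %% thin == 0L)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = .data$fst)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = thr, colour = "red", linetype = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "FST") +
    ggplot2::theme_minimal()
}

#' Windowed heterozygosity along the genome
#'
#' @param windows Output of [windowed_he()].
#' @param q Quantile to mark (default 0.99).
#' @return A ggplot (one line per pool).
#' @export
plot_windowed_he <- function(windows, q = 0.99) {
  thr <- quantile_threshold(windows$he_bar, q)
  ggplot2::ggplot(windows,
                  ggplot2::aes(x = .data$start, y = .data$he_bar,
                               colour = .data$pool_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = thr, colour = "red", linetype = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "window start (bp)", y = "windowed expected heterozygosity",
                  colour = "pool") +
    ggplot2::theme_minimal()
}

#' Cross-species gene score scatter with extreme-quantile guides
#'
#' Each point is an ortholog pair; dashed guides mark per-species upper and
#' lower quantiles, so points in the shared corners are genes with extreme
#' scores in both species.
#'
#' @param pair_table Matched score table from [ortholog_score_table()].
#' @param upper_q,lower_q Guide quantiles (defaults 0.95, 0.05).
#' @return A ggplot.
#' @export
plot_gene_pair <- function(pair_table, upper_q = 0.95, lower_q = 0.05) {
  ggplot2::ggplot(pair_table,
                  ggplot2::aes(x = .data$score_a, y = .data$score_b)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_vline(xintercept = c(quantile_threshold(pair_table$score_a, lower_q),
                                       quantile_threshold(pair_table$score_a, upper_q)),
                        linetype = 2, colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(quantile_threshold(pair_table$score_b, lower_q),
                                       quantile_threshold(pair_table$score_b, upper_q)),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "species A gene score", y = "species B gene score") +
    ggplot2::theme_minimal()
}

#' Heatmap of the population heterozygosity correlation matrix
#'
#' @param mat Tibble from [population_he_matrix()].
#' @return A ggplot tile plot with significance tiers as text.
#' @export
plot_he_matrix <- function(mat) {
  ggplot2::ggplot(mat, ggplot2::aes(x = .data$pool_a, y = .data$pool_b,
                                    fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$tier), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}
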