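#' Average per-SNP FST within each gene
#'
#' Collects, for every annotated gene, the non-missing per-SNP FST values of
#' SNPs falling inside the gene interval (`start <= pos0 < end` in 0-based
#' coordinates, i.e. 1-based `pos` in `(start, end]`), and averages them.
#' Genes without SNPs are kept with a missing mean so that downstream joins
#' stay total. When `fst` contains several pool pairs, values from all pairs
#' are pooled into the gene list.
#'
#' @param genes Gene annotation tibble from [read_gff_genes()].
#' @param fst Per-SNP FST tibble from [snp_fst()].
#' @return Tibble of `gene_id`, `chrom`, `start`, `end`, `n_snps`,
#'   `mean_fst` and the list-column `snp_fst` with each gene's FST values
#'   (used by [null_w_test()]).
#' @export
gene_mean_fst <- function(genes, fst) {
  fst_ok <- fst |>
    dplyr::filter(!is.na(.data$fst)) |>
    dplyr::mutate(pos0 = .data$pos - 1L) |>
    dplyr::select("chrom", "pos0", "fst")
  hits <- dplyr::inner_join(
    genes, fst_ok,
    by = dplyr::join_by("chrom", "start" <= "pos0", "end" > "pos0")
  ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      mean_fst = mean(.data$fst),
      snp_fst = list(.data$fst),
      .groups = "drop"
    )
  genes |>
    dplyr::left_join(hits, by = "gene_id") |>
    dplyr::mutate(
      n_snps = dplyr::coalesce(.data$n_snps, 0L),
      snp_fst = purrr::map2(.data$snp_fst, .data$n_snps,
                            ~ if (is.null(.x)) numeric(0) else .x)
    ) |>
    dplyr::select("gene_id", "chrom", "start", "end", "n_snps", "mean_fst", "snp_fst")
}

#' Assign windowed heterozygosity scores to genes
#'
#' Windows are much wider than genes, so per-gene heterozygosity cannot be
#' estimated directly; instead each gene inherits the score of the window
#' it overlaps most (in base pairs). A gene split exactly 50/50 between two
#' windows takes the left (lower-coordinate) window. Neighbouring genes
#' sharing a window therefore share a score — accepted pseudoreplication.
#'
#' @param genes Gene annotation tibble (or output of [gene_mean_fst()]).
#' @param windows Windowed scores from [windowed_he()].
#' @return Tibble of `gene_id`, `pool_id`, `he`, `window_start`,
#'   `window_end`, one row per gene x pool; genes on chromosomes with no
#'   windows get no rows.
#' @export
assign_window_he <- function(genes, windows) {
  win <- windows |>
    dplyr::distinct(.data$chrom, .data$start, .data$end)
  best <- dplyr::inner_join(
    genes |> dplyr::select("gene_id", "chrom", "start", "end"),
    win,
    by = dplyr::join_by("chrom", "start" < "end", "end" > "start"),
    suffix = c("", "_w")
  ) |>
    dplyr::mutate(overlap = pmin(.data$end, .data$end_w) - pmax(.data$start, .data$start_w)) |>
    dplyr::group_by(.data$gene_id) |>
    # max overlap, ties to the left window
    dplyr::arrange(dplyr::desc(.data$overlap), .data$start_w, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chrom", window_start = "start_w", window_end = "end_w")
  best |>
    dplyr::inner_join(windows,
                      by = c("chrom", window_start = "start", window_end = "end")) |>
    dplyr::select("gene_id", "pool_id", "he" = "he_bar", "window_start", "window_end")
}

#' Filter an ortholog table down to reliable one-to-one pairs
#'
#' Three passes, in a fixed order: (1) drop alignments with mapping quality
#' below `min_mapq` or percent identity below `min_identity`; (2) drop every
#' pair whose gene (on either side) still occurs in more than one surviving
#' pair, removing 1:many and many:many relations; (3) drop pairs whose gene
#' interval overlaps another annotated gene's interval within its own
#' species (any base-pair overlap). The result is a bijection: each gene id
#' occurs at most once per side.
#'
#' @param pairs Ortholog tibble from [read_ortholog_table()].
#' @param genes_a,genes_b Gene annotation tibbles for the two species
#'   (used to resolve intervals for the overlap rule). Pairs whose gene id
#'   cannot be resolved are dropped with a warning count.
#' @param min_mapq Minimum mapping quality (default 80).
#' @param min_identity Minimum percent identity (default 90).
#' @return The surviving rows of `pairs`.
#' @export
filter_orthologs <- function(pairs, genes_a, genes_b,
                             min_mapq = 80, min_identity = 90) {
  unresolved <- sum(!(pairs$gene_a %in% genes_a$gene_id) |
                      !(pairs$gene_b %in% genes_b$gene_id))
  if (unresolved > 0L) {
    warning(unresolved, " ortholog pair(s) dropped: gene id not in annotation",
            call. = FALSE)
    pairs <- pairs |>
      dplyr::filter(.data$gene_a %in% genes_a$gene_id,
                    .data$gene_b %in% genes_b$gene_id)
  }
  kept <- pairs |>
    dplyr::filter(.data$mapping_quality >= min_mapq,
                  .data$percent_identity >= min_identity)
  # multiplicity judged simultaneously on the quality-surviving set
  kept <- kept |>
    dplyr::add_count(.data$gene_a, name = "..n_a") |>
    dplyr::add_count(.data$gene_b, name = "..n_b") |>
    dplyr::filter(.data$..n_a == 1L, .data$..n_b == 1L) |>
    dplyr::select(-"..n_a", -"..n_b")
  overlapping_a <- overlapping_gene_ids(genes_a)
  overlapping_b <- overlapping_gene_ids(genes_b)
  kept |>
    dplyr::filter(!.data$gene_a %in% overlapping_a,
                  !.data$gene_b %in% overlapping_b)
}

# gene ids whose interval overlaps any other gene's interval on the same chrom
overlapping_gene_ids <- function(genes) {
  ov <- dplyr::inner_join(
    genes |> dplyr::select("gene_id", "chrom", "start", "end"),
    genes |> dplyr::select("gene_id", "chrom", "start", "end"),
    by = dplyr::join_by("chrom", "start" < "end", "end" > "start"),
    suffix = c("", "_o")
  ) |>
    dplyr::filter(.data$gene_id != .data$gene_id_o)
  unique(ov$gene_id)
}
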