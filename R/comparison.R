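#' Pair gene-level scores across two species through an ortholog map
#'
#' Builds the matched table that the cross-species comparisons operate on:
#' one row per surviving 1:1 ortholog pair, with a score for each side.
#'
#' @param genes_a,genes_b Gene-level tibbles with `gene_id` and the score
#'   column named by `score`.
#' @param orthologs Filtered ortholog tibble (`gene_a`, `gene_b`).
#' @param score Name of the score column (e.g. `"mean_fst"` or `"he"`).
#' @return Tibble of `gene_a`, `gene_b`, `score_a`, `score_b` with
#'   non-missing scores on both sides.
#' @export
ortholog_score_table <- function(genes_a, genes_b, orthologs, score = "mean_fst") {
  a <- genes_a |> dplyr::select("gene_id", score_a = dplyr::all_of(score))
  b <- genes_b |> dplyr::select("gene_id", score_b = dplyr::all_of(score))
  orthologs |>
    dplyr::select("gene_a", "gene_b") |>
    dplyr::inner_join(a, by = c(gene_a = "gene_id")) |>
    dplyr::inner_join(b, by = c(gene_b = "gene_id")) |>
    dplyr::filter(!is.na(.data$score_a), !is.na(.data$score_b))
}

#' Spearman correlation of gene scores between two species
#'
#' Rank correlation (midranks for ties) of matched ortholog scores, with
#' the large-sample t approximation for the p-value. Per-gene
#' heterozygosity scores should be averaged across each species'
#' populations before they enter this comparison.
#'
#' @param pair_table Matched score table from [ortholog_score_table()]
#'   (columns `score_a`, `score_b`).
#' @return One-row tibble: `rho`, `p_value`, `n_genes`. `rho` is missing
#'   (with a warning) when either side is constant.
#' @export
spearman_gene_correlation <- function(pair_table) {
  x <- pair_table$score_a
  y <- pair_table$score_b
  n <- length(x)
  if (n < 3L) stop("need at least 3 matched gene pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant scores on one side; rho undefined", call. = FALSE)
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n_genes = n))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n_genes = n)
}

#' Spearman correlation matrix of windowed heterozygosity across populations
#'
#' Within a species, two pools are compared directly over their shared
#' genomic windows. Across species, windows are not homologous, so scores
#' are projected onto genes first (each gene carries its window's score,
#' see [assign_window_he()]) and populations are compared over
#' ortholog-linked genes. The matrix is symmetric with a unit diagonal;
#' significance tiers mark p < .05, < .01, < .001.
#'
#' @param windows Named list of [windowed_he()] outputs, one per species.
#' @param gene_he Named list of [assign_window_he()] outputs, one per
#'   species.
#' @param ortholog_pairs Named list of filtered ortholog tibbles; the name
#'   `"spA|spB"` links `gene_a` in species `spA` to `gene_b` in `spB`.
#' @return Tibble of `pool_a`, `pool_b`, `rho`, `p_value`, `tier` for every
#'   unordered pool pair (both orders present; diagonal rho = 1).
#' @export
population_he_matrix <- function(windows, gene_he, ortholog_pairs = list()) {
  species <- names(windows)
  pools <- purrr::map_dfr(species, function(sp) {
    tibble::tibble(species = sp, pool_id = unique(windows[[sp]]$pool_id))
  })

  score_pair <- function(sp1, p1, sp2, p2) {
    if (sp1 == sp2) {
      w <- windows[[sp1]]
      tab <- dplyr::inner_join(
        w |> dplyr::filter(.data$pool_id == p1) |>
          dplyr::select("chrom", "start", x = "he_bar"),
        w |> dplyr::filter(.data$pool_id == p2) |>
          dplyr::select("chrom", "start", y = "he_bar"),
        by = c("chrom", "start")
      )
    } else {
      key <- paste0(sp1, "|", sp2)
      rkey <- paste0(sp2, "|", sp1)
      if (!is.null(ortholog_pairs[[key]])) {
        orth <- ortholog_pairs[[key]]
      } else if (!is.null(ortholog_pairs[[rkey]])) {
        orth <- ortholog_pairs[[rkey]] |>
          dplyr::rename(gene_a = "gene_b", gene_b = "gene_a")
      } else {
        return(NULL)
      }
      tab <- orth |>
        dplyr::inner_join(
          gene_he[[sp1]] |> dplyr::filter(.data$pool_id == p1) |>
            dplyr::select("gene_id", x = "he"),
          by = c(gene_a = "gene_id")
        ) |>
        dplyr::inner_join(
          gene_he[[sp2]] |> dplyr::filter(.data$pool_id == p2) |>
            dplyr::select("gene_id", y = "he"),
          by = c(gene_b = "gene_id")
        )
    }
    tab <- tab |> dplyr::filter(!is.na(.data$x), !is.na(.data$y))
    if (nrow(tab) < 3L) return(NULL)
    ct <- suppressWarnings(cor.test(tab$x, tab$y, method = "spearman", exact = FALSE))
    tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
  }

  grid <- tidyr::expand_grid(
    a = seq_len(nrow(pools)), b = seq_len(nrow(pools))
  )
  out <- purrr::pmap_dfr(grid, function(a, b) {
    pa <- pools[a, ]
    pb <- pools[b, ]
    if (a == b) {
      cell <- tibble::tibble(rho = 1, p_value = 0)
    } else {
      cell <- score_pair(pa$species, pa$pool_id, pb$species, pb$pool_id)
      if (is.null(cell)) cell <- tibble::tibble(rho = NA_real_, p_value = NA_real_)
    }
    tibble::tibble(pool_a = pa$pool_id, pool_b = pb$pool_id,
                   rho = cell$rho, p_value = cell$p_value)
  })
  out |>
    dplyr::mutate(tier = dplyr::case_when(
      is.na(.data$p_value) ~ "",
      .data$p_value < 0.001 ~ "***",
      .data$p_value < 0.01 ~ "**",
      .data$p_value < 0.05 ~ "*",
      TRUE ~ ""
    ))
}

#' Count genes with shared extreme scores in two species
#'
#' Per-species nearest-rank quantile thresholds are computed over the
#' matched ortholog set; the function counts genes strictly above the upper
#' threshold in BOTH species and strictly below the lower threshold in
#' both.
#'
#' @param pair_table Matched score table from [ortholog_score_table()].
#' @param upper_q Upper quantile (default 0.95).
#' @param lower_q Lower quantile (default 0.05).
#' @return One-row tibble: `shared_upper`, `shared_lower`, `n_genes`, plus
#'   the four thresholds.
#' @export
extreme_overlap <- function(pair_table, upper_q = 0.95, lower_q = 0.05) {
  ua <- quantile_threshold(pair_table$score_a, upper_q)
  ub <- quantile_threshold(pair_table$score_b, upper_q)
  la <- quantile_threshold(pair_table$score_a, lower_q)
  lb <- quantile_threshold(pair_table$score_b, lower_q)
  tibble::tibble(
    shared_upper = sum(pair_table$score_a > ua & pair_table$score_b > ub),
    shared_lower = sum(pair_table$score_a < la & pair_table$score_b < lb),
    n_genes = nrow(pair_table),
    upper_a = ua, upper_b = ub, lower_a = la, lower_b = lb
  )
}
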