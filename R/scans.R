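#' Flag per-SNP FST outliers against a genome-wide quantile
#'
#' The outlier threshold is the empirical `q`-quantile (nearest-rank, see
#' [quantile_threshold()]) of all non-missing per-SNP FST values in the
#' species; a SNP is an outlier iff its FST lies strictly above the
#' threshold. The default `q = 0.999` flags roughly the top 0.1% of SNPs.
#'
#' @param fst Per-SNP FST tibble from [snp_fst()].
#' @param q Outlier quantile (default 0.999).
#' @return `fst` with a logical `outlier` column; the threshold is attached
#'   as attribute `"fst_threshold"`.
#' @export
fst_outlier_flags <- function(fst, q = 0.999) {
  vals <- fst$fst[!is.na(fst$fst)]
  if (!length(vals)) stop("no non-missing FST values", call. = FALSE)
  if (length(vals) < 1000L) {
    warning("fewer than 1000 SNPs; the ", q,
            " outlier quantile will be unstable", call. = FALSE)
  }
  thr <- quantile_threshold(vals, q)
  out <- fst |>
    dplyr::mutate(outlier = !is.na(.data$fst) & .data$fst > thr)
  attr(out, "fst_threshold") <- thr
  out
}

#' Binomial candidate threshold for the top-candidate test
#'
#' With `n_snps` SNPs in a gene and a per-SNP outlier probability
#' `p_success`, the number of outliers expected by chance is binomial; the
#' candidate threshold is the `q`-quantile of that distribution — the
#' smallest integer `k` with `P(X <= k) >= q` — and a gene is a candidate
#' only when its observed outlier count strictly exceeds it.
#'
#' @param n_snps Number of SNPs in the gene (vectorised).
#' @param p_success Per-SNP outlier probability (default 0.001).
#' @param q Quantile of the binomial null (default 0.999).
#' @return Integer vector of thresholds.
#' @examples
#' binom_candidate_threshold(1000) # 5
#' @export
binom_candidate_threshold <- function(n_snps, p_success = 0.001, q = 0.999) {
  stopifnot(all(n_snps >= 1L), p_success >= 0, p_success <= 1)
  as.integer(qbinom(q, size = n_snps, prob = p_success))
}

#' Top-candidate genes for local adaptation
#'
#' Counts, per gene, the SNPs flagged as species-wide FST outliers and
#' compares the count against the binomial expectation from
#' [binom_candidate_threshold()]. Genes whose observed count strictly
#' exceeds the threshold are top candidates. SNPs with missing FST are in
#' neither the SNP count nor the outlier count.
#'
#' @param genes Gene annotation tibble.
#' @param flagged_fst Output of [fst_outlier_flags()].
#' @param p_success Per-SNP outlier probability (default 0.001).
#' @param q Quantile of the binomial null (default 0.999).
#' @return A tibble of class `poolscan_topcand`: `gene_id`, `chrom`,
#'   `start`, `end`, `n_snps`, `n_outliers`, `binom_threshold` (missing for
#'   SNP-less genes), `is_candidate`. Attributes record the FST outlier
#'   threshold and the parameters. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
top_candidates <- function(genes, flagged_fst, p_success = 0.001, q = 0.999) {
  ok <- flagged_fst |>
    dplyr::filter(!is.na(.data$fst)) |>
    dplyr::mutate(pos0 = .data$pos - 1L) |>
    dplyr::select("chrom", "pos0", "outlier")
  per_gene <- dplyr::inner_join(
    genes, ok,
    by = dplyr::join_by("chrom", "start" <= "pos0", "end" > "pos0")
  ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_snps = dplyr::n(),
                     n_outliers = sum(.data$outlier), .groups = "drop")
  res <- genes |>
    dplyr::select("gene_id", "chrom", "start", "end") |>
    dplyr::left_join(per_gene, by = "gene_id") |>
    dplyr::mutate(
      n_snps = dplyr::coalesce(.data$n_snps, 0L),
      n_outliers = dplyr::coalesce(.data$n_outliers, 0L),
      binom_threshold = dplyr::if_else(
        .data$n_snps > 0L,
        binom_candidate_threshold(pmax(.data$n_snps, 1L), p_success, q),
        NA_integer_
      ),
      is_candidate = !is.na(.data$binom_threshold) &
        .data$n_outliers > .data$binom_threshold
    )
  structure(
    res,
    fst_threshold = attr(flagged_fst, "fst_threshold"),
    p_success = p_success,
    q = q,
    class = c("poolscan_topcand", class(res))
  )
}

#' @exportS3Method generics::tidy
tidy.poolscan_topcand <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @exportS3Method generics::glance
glance.poolscan_topcand <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_genes_with_snps = sum(x$n_snps > 0L),
    n_candidates = sum(x$is_candidate),
    fst_threshold = attr(x, "fst_threshold") %||% NA_real_,
    p_success = attr(x, "p_success"),
    q = attr(x, "q")
  )
}

#' Plot a top-candidate scan
#'
#' SNP count per gene against outlier count, with the jagged binomial
#' decision boundary; candidate genes sit above the line.
#'
#' @param object A `poolscan_topcand` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot poolscan_topcand
#' @export
autoplot.poolscan_topcand <- function(object, ...) {
  dat <- tidy(object) |> dplyr::filter(.data$n_snps > 0L)
  ns <- seq(1L, max(dat$n_snps), length.out = min(400L, max(dat$n_snps)))
  ns <- unique(as.integer(ns))
  boundary <- tibble::tibble(
    n_snps = ns,
    thr = binom_candidate_threshold(ns, attr(object, "p_success"), attr(object, "q"))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_snps, y = .data$n_outliers)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_candidate), alpha = 0.6) +
    ggplot2::geom_step(data = boundary, ggplot2::aes(y = .data$thr),
                       colour = "red", linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(x = "SNPs in gene", y = "FST outliers in gene",
                  colour = "top candidate") +
    ggplot2::theme_minimal()
}
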