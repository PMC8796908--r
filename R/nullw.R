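#' Draw the shared control-SNP set for the Null-W test
#'
#' A single standard set of control SNPs (default 10,000), sampled uniformly
#' without replacement from the non-missing per-SNP FST values of the focal
#' species, is reused for every test gene and every null gene within one
#' run, so all W-scores are comparable. Deterministic under `seed`.
#'
#' @param fst Per-SNP FST tibble from [snp_fst()] (or a numeric vector of
#'   FST values).
#' @param n Number of control SNPs (default 10,000).
#' @param seed Integer seed.
#' @return Numeric vector of control FST values.
#' @export
draw_control_snps <- function(fst, n = 10000L, seed) {
  vals <- if (is.data.frame(fst)) fst$fst else fst
  vals <- vals[!is.na(vals)]
  if (length(vals) < n) {
    warning("only ", length(vals), " non-missing FST values available; ",
            "using all of them as controls", call. = FALSE)
    n <- length(vals)
  }
  withr_seed(seed, sample(vals, size = n, replace = FALSE))
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Wilcoxon rank-sum W and normal Z for one gene against controls
#'
#' `W` is the Mann-Whitney U statistic of the gene group: the number of
#' (gene SNP, control SNP) pairs in which the gene value ranks higher, ties
#' counting one half. It is standardised to
#' `Z = (W - n1 n2 / 2) / sqrt(var)`, where `var` is the usual rank-sum
#' variance `n1 n2 (n1 + n2 + 1) / 12`, with the standard tie correction
#' `n1 n2 / 12 * (n + 1 - sum(t^3 - t) / (n (n - 1)))` when ties are
#' present. No continuity correction is applied. Large positive Z means the
#' gene's FST values sit above the control distribution.
#'
#' @param gene_fst Numeric vector of the gene's per-SNP FST values.
#' @param control_fst Numeric vector of control FST values.
#' @return Named numeric vector `c(W, Z)`.
#' @examples
#' wilcoxon_w_z(c(4, 5, 6), c(1, 2, 3)) # W = 9, Z = 1.964
#' @export
wilcoxon_w_z <- function(gene_fst, control_fst) {
  stopifnot(length(gene_fst) >= 1L, length(control_fst) >= 1L)
  n1 <- length(gene_fst)
  n2 <- length(control_fst)
  n <- n1 + n2
  r <- rank(c(gene_fst, control_fst))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- tabulate_ties(r)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (v > 0) (w - n1 * n2 / 2) / sqrt(v) else 0
  c(W = w, Z = z)
}

tabulate_ties <- function(r) {
  t <- rle(sort(r))$lengths
  as.numeric(t[t > 1L])
}

#' Null-W test for convergent evolution between two species
#'
#' Direction is explicit: top candidates come from species A; divergence is
#' evaluated in species B. The orthologs (in B) of A's candidates form the
#' test set; their per-SNP FST values in B are each compared with a shared
#' control-SNP set via [wilcoxon_w_z()], as are the genes of a null set
#' drawn from the rest of the orthologous genes. A test gene's empirical
#' p-value is its position in the null Z distribution,
#' `(1 + #\{null Z >= test Z\}) / (1 + N_null)` (one-sided: high FST in B
#' is the signal), Bonferroni-corrected over the number of test genes.
#'
#' @param candidates_a A `poolscan_topcand` result for species A.
#' @param orthologs Filtered 1:1 ortholog tibble ([filter_orthologs()]),
#'   `gene_a` in species A, `gene_b` in species B.
#' @param genes_b Gene-level FST for species B from [gene_mean_fst()]
#'   (needs the `snp_fst` list-column).
#' @param fst_b Per-SNP FST tibble for species B (source of control SNPs).
#' @param n_control Size of the shared control-SNP set (default 10,000).
#' @param null_gene_set `"all_noncandidate_orthologs"` (default,
#'   deterministic) or `"random_k"` (sample `n_null_genes` of them).
#' @param n_null_genes Null-set size for `"random_k"`.
#' @param min_snps_per_gene Minimum SNPs for a gene to be scored (default 1).
#' @param seed Integer seed for the control draw (and null-set draw).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble of class `poolscan_nullw`: `gene_a`, `gene_b`,
#'   `n_gene_snps`, `W`, `Z`, `emp_p`, `adj_p`, `significant`. The null
#'   gene Z-scores, control set size and parameters are attached as
#'   attributes. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
null_w_test <- function(candidates_a, orthologs, genes_b, fst_b,
                        n_control = 10000L,
                        null_gene_set = c("all_noncandidate_orthologs", "random_k"),
                        n_null_genes = 1000L, min_snps_per_gene = 1L,
                        seed = 1L, alpha = 0.05) {
  null_gene_set <- match.arg(null_gene_set)
  cand_ids <- candidates_a$gene_id[candidates_a$is_candidate]
  scored_b <- genes_b |>
    dplyr::filter(.data$n_snps >= min_snps_per_gene)

  test_tab <- orthologs |>
    dplyr::filter(.data$gene_a %in% cand_ids) |>
    dplyr::inner_join(scored_b, by = c(gene_b = "gene_id"))
  null_tab <- orthologs |>
    dplyr::filter(!.data$gene_a %in% cand_ids) |>
    dplyr::inner_join(scored_b, by = c(gene_b = "gene_id"))

  empty <- tibble::tibble(
    gene_a = character(), gene_b = character(), n_gene_snps = integer(),
    W = numeric(), Z = numeric(), emp_p = numeric(), adj_p = numeric(),
    significant = logical()
  )
  if (!nrow(test_tab)) {
    warning("no orthologs of top candidates are scorable in species B; ",
            "empty Null-W result", call. = FALSE)
    return(new_nullw(empty, numeric(0), 0L, alpha))
  }

  controls <- draw_control_snps(fst_b, n_control, seed)

  if (null_gene_set == "random_k" && nrow(null_tab) > n_null_genes) {
    idx <- withr_seed(seed + 1L, sample.int(nrow(null_tab), n_null_genes))
    null_tab <- null_tab[idx, ]
  }
  if (nrow(null_tab) < 100L) {
    warning("only ", nrow(null_tab),
            " null genes; empirical p-values will be unstable", call. = FALSE)
  }

  z_of <- function(lst) {
    vapply(lst, function(v) wilcoxon_w_z(v, controls), c(W = 0, Z = 0))
  }
  test_wz <- z_of(test_tab$snp_fst)
  null_z <- if (nrow(null_tab)) z_of(null_tab$snp_fst)["Z", ] else numeric(0)

  n_null <- length(null_z)
  emp_p <- vapply(unname(test_wz["Z", ]),
                  function(z) (1 + sum(null_z >= z)) / (1 + n_null),
                  numeric(1))
  res <- tibble::tibble(
    gene_a = test_tab$gene_a,
    gene_b = test_tab$gene_b,
    n_gene_snps = test_tab$n_snps,
    W = unname(test_wz["W", ]),
    Z = unname(test_wz["Z", ]),
    emp_p = emp_p,
    adj_p = pmin(1, emp_p * nrow(test_tab)),
    significant = pmin(1, emp_p * nrow(test_tab)) < alpha
  )
  new_nullw(res, null_z, length(controls), alpha)
}

new_nullw <- function(res, null_z, n_control, alpha) {
  structure(res,
            null_z = null_z, n_control = n_control, alpha = alpha,
            class = c("poolscan_nullw", class(res)))
}

#' @exportS3Method generics::tidy
tidy.poolscan_nullw <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @exportS3Method generics::glance
glance.poolscan_nullw <- function(x, ...) {
  tibble::tibble(
    n_test_genes = nrow(x),
    n_null_genes = length(attr(x, "null_z")),
    n_control_snps = attr(x, "n_control"),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha")
  )
}

#' Plot a Null-W result
#'
#' Density of the null gene Z-scores with the test genes overlaid as
#' points (jittered vertically) and the 95th null quantile marked.
#'
#' @param object A `poolscan_nullw` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot poolscan_nullw
#' @export
autoplot.poolscan_nullw <- function(object, ...) {
  null_df <- tibble::tibble(Z = attr(object, "null_z"))
  q95 <- quantile_threshold(null_df$Z, 0.95)
  test_df <- tidy(object)
  ggplot2::ggplot(null_df, ggplot2::aes(x = .data$Z)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey40") +
    ggplot2::geom_jitter(
      data = test_df,
      ggplot2::aes(y = 0, colour = .data$significant),
      height = 0.02, width = 0, alpha = 0.8
    ) +
    ggplot2::geom_vline(xintercept = q95, colour = "red", linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue", `TRUE` = "red")) +
    ggplot2::labs(x = "Z score vs control SNPs", y = "null density",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
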