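#' Post-calling SNP filter configuration
#'
#' Defaults mirror the standard Pool-seq post-calling filters: drop
#' multiallelic sites, require total coverage of at least 50 reads and site
#' quality of at least 20, and require the minor allele to reach a pooled
#' frequency of 0.01 with at least 2 supporting reads. Coverage and the
#' minor-allele rules are evaluated on read counts summed across all pools
#' of the species (the multi-sample mpileup view the caller saw);
#' `per_pool_coverage = TRUE` switches to the stricter per-pool minimum.
#'
#' @param min_coverage Minimum summed read depth across pools.
#' @param min_quality Minimum site quality (QUAL).
#' @param min_maf Minimum pooled minor-allele frequency, in `[0, 0.5]`.
#' @param min_minor_reads Minimum summed read count for the minor allele.
#' @param drop_multiallelic Drop sites with more than one ALT allele?
#' @param per_pool_coverage Apply `min_coverage` to every pool separately?
#' @return A list of class `poolscan_filter_config`.
#' @export
filter_config <- function(min_coverage = 50L, min_quality = 20, min_maf = 0.01,
                          min_minor_reads = 2L, drop_multiallelic = TRUE,
                          per_pool_coverage = FALSE) {
  stopifnot(min_coverage >= 0, min_quality >= 0, min_minor_reads >= 0,
            min_maf >= 0, min_maf <= 0.5)
  structure(
    list(min_coverage = min_coverage, min_quality = min_quality,
         min_maf = min_maf, min_minor_reads = min_minor_reads,
         drop_multiallelic = drop_multiallelic,
         per_pool_coverage = per_pool_coverage),
    class = "poolscan_filter_config"
  )
}

#' Filter pooled variants
#'
#' Applies the post-calling SNP filters to a long site x pool count table.
#' A site passes iff it is biallelic, its summed depth and quality clear the
#' thresholds, and the pooled minor allele clears both the frequency and the
#' read-count floor. Sites that fail are attributed to the FIRST failing
#' rule in the fixed order multiallelic, coverage, quality, maf,
#' min_minor_reads, so the removal report is deterministic.
#'
#' @param variants Long variant tibble from [read_pooled_vcf()] or
#'   [simulate_species()].
#' @param cfg A [filter_config()].
#' @return The passing rows of `variants`, with the removal report attached
#'   as attribute `"filter_report"` (retrieve with [filter_report()]): a
#'   tibble of `rule`, `n_removed` plus rows for input and passing site
#'   counts. Counts are per site, not per row.
#' @examples
#' \dontrun{
#' kept <- filter_variants(variants, filter_config())
#' filter_report(kept)
#' }
#' @export
filter_variants <- function(variants, cfg = filter_config()) {
  if (!nrow(variants)) {
    report <- tibble::tibble(
      rule = c("input", "multiallelic", "coverage", "quality", "maf",
               "min_minor_reads", "passed"),
      n_sites = 0L
    )
    attr(variants, "filter_report") <- report
    return(variants)
  }
  site_stats <- variants |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      n_alt = .data$n_alt[1],
      qual = .data$qual[1],
      depth = sum(.data$ref_reads + .data$alt_reads),
      min_pool_depth = min(.data$ref_reads + .data$alt_reads),
      alt_total = sum(.data$alt_reads),
      ref_total = sum(.data$ref_reads),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      minor_reads = pmin(.data$alt_total, .data$ref_total),
      maf = dplyr::if_else(.data$depth > 0, .data$minor_reads / .data$depth, NA_real_)
    )

  cov_ok <- if (cfg$per_pool_coverage) {
    site_stats$min_pool_depth >= cfg$min_coverage
  } else {
    site_stats$depth >= cfg$min_coverage
  }
  fails <- cbind(
    multiallelic = cfg$drop_multiallelic & site_stats$n_alt > 1L,
    coverage = !cov_ok,
    quality = !(site_stats$qual >= cfg$min_quality) | is.na(site_stats$qual),
    maf = !(site_stats$maf >= cfg$min_maf) | is.na(site_stats$maf),
    min_minor_reads = site_stats$minor_reads < cfg$min_minor_reads
  )
  first_fail <- apply(fails, 1L, function(f) {
    i <- which(f)
    if (length(i)) colnames(fails)[i[1]] else NA_character_
  })

  rules <- colnames(fails)
  report <- tibble::tibble(
    rule = c("input", rules, "passed"),
    n_sites = c(
      nrow(site_stats),
      unname(vapply(rules, function(r) sum(first_fail == r, na.rm = TRUE), integer(1))),
      sum(is.na(first_fail))
    )
  )

  keep_sites <- site_stats[is.na(first_fail), c("chrom", "pos")]
  out <- dplyr::semi_join(variants, keep_sites, by = c("chrom", "pos"))
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the removal report attached by [filter_variants()]
#'
#' @param variants The tibble returned by [filter_variants()].
#' @return A tibble with one row per filter rule plus input/passed totals.
#' @export
filter_report <- function(variants) {
  rep <- attr(variants, "filter_report")
  if (is.null(rep)) stop("no filter report attached; was this produced by filter_variants()?",
                         call. = FALSE)
  rep
}
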