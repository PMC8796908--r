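#' Build a population-pool metadata table
#'
#' Pool-seq analyses need to know, for every sequenced pool, how many diploid
#' individuals went into it (the haploid size of the pool is `2 * n_individuals`)
#' and which side of the latitudinal contrast it represents. All downstream
#' functions take this table as their description of the sampling design.
#'
#' @param pool_id Character vector of unique pool labels. These must match the
#'   sample names in the VCF.
#' @param species Character vector, species label per pool.
#' @param n_individuals Positive integer vector, diploid individuals per pool.
#' @param latitude_class Character vector, `"north"` or `"south"` per pool.
#'
#' @return A tibble with columns `pool_id`, `species`, `n_individuals`,
#'   `latitude_class` and `ploidy` (`= 2 * n_individuals`).
#' @examples
#' pool_meta(
#'   pool_id = c("TsAK", "TsOR"), species = "threespine",
#'   n_individuals = c(52, 51), latitude_class = c("north", "south")
#' )
#' @export
pool_meta <- function(pool_id, species, n_individuals, latitude_class) {
  meta <- tibble::tibble(
    pool_id = as.character(pool_id),
    species = as.character(species),
    n_individuals = as.integer(n_individuals),
    latitude_class = as.character(latitude_class)
  )
  if (anyDuplicated(meta$pool_id)) {
    stop("pool_id labels must be unique", call. = FALSE)
  }
  if (any(meta$n_individuals < 1L)) {
    stop("n_individuals must be positive", call. = FALSE)
  }
  bad <- setdiff(unique(meta$latitude_class), c("north", "south"))
  if (length(bad)) {
    stop("latitude_class must be 'north' or 'south', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  meta$ploidy <- 2L * meta$n_individuals
  singletons <- meta |>
    dplyr::count(.data$species) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(singletons)) {
    warning("species with a single pool (no within-species contrast possible): ",
            paste(singletons$species, collapse = ", "), call. = FALSE)
  }
  meta
}

#' Read pooled variant calls from a VCF
#'
#' Parses a VCF whose per-sample fields carry pooled ref/alt read depths and
#' returns one row per site x pool, the long "tidy" shape every downstream
#' statistic consumes. Genotype calls are ignored: Pool-seq semantics are
#' count-based. Two depth encodings are understood: a two-value `AD`
#' (`ref,alt`, GATK-style) or separate `RD`/`AD` fields (VarScan-style).
#' Multiallelic records are returned (with `n_alt > 1`, counts taken for the
#' first ALT allele) so that filtering can happen, and be reported, downstream.
#'
#' @param path Path to a VCF (v4.x, plain text or gzipped).
#' @param meta Pool metadata from [pool_meta()]. Every `pool_id` must be a
#'   sample column in the VCF; sample order in the file is irrelevant.
#'
#' @return A tibble with one row per site x pool: `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `qual`, `n_alt` (number of ALT alleles at the site),
#'   `pool_id`, `ref_reads`, `alt_reads`.
#' @seealso [filter_variants()], [snp_frequencies()]
#' @export
read_pooled_vcf <- function(path, meta) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(meta$pool_id, samples)
  if (length(missing)) {
    stop("VCF is missing sample column(s) for declared pool(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_site <- nrow(fix)
  fmt_has <- function(key) {
    any(grepl(paste0("(^|:)", key, "(:|$)"), vcf@gt[, "FORMAT"]))
  }
  if (!fmt_has("AD")) {
    stop("VCF FORMAT lacks an AD depth field; pooled read depths are required",
         call. = FALSE)
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  rd <- if (fmt_has("RD")) vcfR::extract.gt(vcf, element = "RD") else NULL

  parse_pool <- function(pool) {
    ad_p <- ad[, pool]
    if (is.null(rd)) {
      # AD carries ref,alt[,alt2...]; take the first two fields
      parts <- stringr::str_split_fixed(ad_p, ",", 3L)
      ref_reads <- suppressWarnings(as.integer(parts[, 1]))
      alt_reads <- suppressWarnings(as.integer(parts[, 2]))
      malformed <- which(!is.na(ad_p) & (is.na(ref_reads) | is.na(alt_reads)))
    } else {
      ref_reads <- suppressWarnings(as.integer(rd[, pool]))
      alt_reads <- suppressWarnings(as.integer(stringr::str_split_fixed(ad_p, ",", 2L)[, 1]))
      malformed <- which(!is.na(ad_p) & is.na(alt_reads))
    }
    if (length(malformed)) {
      stop("malformed depth field for pool '", pool, "' at VCF record(s) ",
           paste(head(malformed, 5L), collapse = ", "), call. = FALSE)
    }
    tibble::tibble(
      site = seq_len(n_site),
      pool_id = pool,
      ref_reads = dplyr::coalesce(ref_reads, 0L),
      alt_reads = dplyr::coalesce(alt_reads, 0L)
    )
  }
  counts <- purrr::map_dfr(meta$pool_id, parse_pool)

  sites <- tibble::tibble(
    site = seq_len(n_site),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = stringr::str_split_fixed(fix$ALT, ",", 2L)[, 1],
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    n_alt = stringr::str_count(fix$ALT, ",") + 1L
  )
  out <- dplyr::inner_join(sites, counts, by = "site") |>
    dplyr::arrange(.data$site, match(.data$pool_id, meta$pool_id)) |>
    dplyr::select(-"site")
  if (any(out$ref_reads < 0L | out$alt_reads < 0L, na.rm = TRUE)) {
    stop("negative read counts in VCF depth fields", call. = FALSE)
  }
  out
}

#' Read gene annotations from a GFF3 file
#'
#' Keeps only `gene`-type features and converts coordinates from GFF3
#' 1-based closed intervals to the 0-based half-open convention used for all
#' interval arithmetic in this package (windows, gene overlap, SNP
#' containment).
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_gff_genes <- function(path) {
  gff <- ape::read.gff(path)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (!nrow(genes)) {
    return(tibble::tibble(
      gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }
  ids <- stringr::str_match(genes$attributes, "ID=([^;]+)")[, 2]
  if (anyNA(ids)) {
    stop("gene feature without an ID attribute in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated gene_id in GFF3: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    gene_id = ids,
    chrom = as.character(genes$seqid),
    start = as.integer(genes$start) - 1L,
    end = as.integer(genes$end),
    strand = as.character(genes$strand)
  )
  out$strand[is.na(out$strand)] <- "."
  if (any(out$start >= out$end)) {
    stop("gene with non-positive length after coordinate conversion", call. = FALSE)
  }
  out
}

#' Read a cross-species ortholog table
#'
#' The table is a pipeline input (ortholog inference itself is out of scope):
#' a TSV with header columns `gene_a`, `gene_b`, `mapping_quality`,
#' `percent_identity`, `relation`. No filtering happens at read time; see
#' [filter_orthologs()].
#'
#' @param path Path to the TSV.
#' @return A tibble with the five schema columns.
#' @export
read_ortholog_table <- function(path) {
  needed <- c("gene_a", "gene_b", "mapping_quality", "percent_identity", "relation")
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("ortholog table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$gene_a <- as.character(tab$gene_a)
  tab$gene_b <- as.character(tab$gene_b)
  tab$relation <- as.character(tab$relation)
  tab$mapping_quality <- suppressWarnings(as.numeric(tab$mapping_quality))
  tab$percent_identity <- suppressWarnings(as.numeric(tab$percent_identity))
  bad_num <- which(is.na(tab$percent_identity) | is.na(tab$mapping_quality))
  if (length(bad_num)) {
    stop("non-numeric mapping_quality/percent_identity at row(s) ",
         paste(head(bad_num, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(tab$percent_identity < 0 | tab$percent_identity > 100)) {
    stop("percent_identity outside [0, 100]", call. = FALSE)
  }
  tab[needed]
}

#' Write a results table as TSV with a provenance header
#'
#' Every writer in the pipeline emits one `#` comment line recording the
#' package version and the parameters that produced the table, then the
#' table itself with a header row. [read_results_tsv()] round-trips these
#' files exactly.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param params Named list of parameters to record in the comment line.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(x, path, params = list()) {
  stamp <- paste0(
    "# poolscan ", as.character(packageVersion("poolscan")),
    if (length(params)) {
      paste0(" | ", paste(names(params), unlist(params), sep = "=", collapse = " "))
    }
  )
  writeLines(stamp, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read back a results table written by [write_results_tsv()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_results_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
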