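# in-code fixtures shared across test files

two_pool_meta <- function(n1 = 50L, n2 = 50L, species = "spA") {
  pool_meta(
    pool_id = paste0(species, c("_n", "_s")),
    species = species,
    n_individuals = c(n1, n2),
    latitude_class = c("north", "south")
  )
}

# long site x pool variant tibble from explicit per-site count vectors
make_variants <- function(meta, ref1, alt1, ref2, alt2,
                          chrom = "chr1", pos = NULL, qual = 50, n_alt = 1L) {
  ns <- length(ref1)
  if (is.null(pos)) pos <- seq_len(ns)
  dplyr::bind_rows(
    tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "T",
                   qual = qual, n_alt = n_alt,
                   pool_id = meta$pool_id[1], ref_reads = ref1, alt_reads = alt1),
    tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "T",
                   qual = qual, n_alt = n_alt,
                   pool_id = meta$pool_id[2], ref_reads = ref2, alt_reads = alt2)
  )
}

# Balding-Nichols count simulation outside the package (independent of
# simulate_species) for estimator checks: returns a long variant tibble
bn_counts <- function(n_snps, f, meta, depth, seed, p0 = NULL) {
  set.seed(seed)
  if (is.null(p0)) p0 <- runif(n_snps, 0.05, 0.95)
  draw_pool <- function(ploidy) {
    p_pop <- if (f > 1e-9) {
      rbeta(n_snps, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    } else {
      p0
    }
    k <- rbinom(n_snps, ploidy, p_pop)
    d <- rpois(n_snps, depth)
    r <- rbinom(n_snps, d, k / ploidy)
    list(ref = d - r, alt = r)
  }
  a <- draw_pool(meta$ploidy[1])
  b <- draw_pool(meta$ploidy[2])
  make_variants(meta, a$ref, a$alt, b$ref, b$alt)
}

# small hand-written VCF fixture (2 pools, 3 records, one multiallelic),
# sample columns deliberately in the order s2, s1
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ref,alt depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s2", "s1"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t55\tPASS\t.\tDP:AD\t30:20,10\t40:25,15",
    "chr1\t200\t.\tC\tG\t31.5\tPASS\t.\tDP:AD\t60:60,0\t50:49,1",
    "chr2\t50\t.\tG\tA,T\t12\tPASS\t.\tDP:AD\t20:10,6,4\t22:12,8,2"
  ), path)
  path
}

toy_vcf_meta <- function() {
  pool_meta(c("s1", "s2"), "spA", c(10L, 12L), c("north", "south"))
}

write_toy_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA;Name=geneA",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t101\t150\t.\t+\t.\tParent=gA.t1",
    "chr1\tsrc\tgene\t301\t450\t.\t-\t.\tID=gB",
    "chr2\tsrc\tgene\t11\t60\t.\t+\t.\tID=gC",
    "chr2\tsrc\tgene\t100\t160\t.\t+\t.\tID=gD",
    "chr2\tsrc\tgene\t500\t760\t.\t-\t.\tID=gE"
  ), path)
  path
}

small_genes <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0L, 100L, 50L),
    end = c(50L, 200L, 150L),
    strand = "+"
  )
}

# minimal flagged-FST table: positions, outlier flags, arbitrary fst values
make_flags <- function(pos, outlier, chrom = "chr1", threshold = 0.5) {
  out <- tibble::tibble(
    chrom = chrom, pos = pos,
    pool_a = "p1", pool_b = "p2",
    fst = ifelse(outlier, threshold + 0.1, threshold - 0.1),
    outlier = outlier
  )
  attr(out, "fst_threshold") <- threshold
  out
}
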