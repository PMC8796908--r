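test_that("gene FST means collect exactly the SNPs inside each interval", {
  genes <- small_genes()
  fst <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(10L, 40L, 150L, 60L, 200L), # 1-based; 0-based pos-1
    pool_a = "p1", pool_b = "p2",
    fst = c(0.1, 0.3, 0.7, 0.2, NA)
  )
  g <- gene_mean_fst(genes, fst)
  expect_equal(g$mean_fst[g$gene_id == "g1"], 0.2) # {0.1, 0.3}
  expect_equal(g$n_snps[g$gene_id == "g1"], 2L)
  expect_equal(g$mean_fst[g$gene_id == "g2"], 0.7)
  # chr2 SNP at pos 200 is outside g3 [50,150) and NA besides
  expect_equal(g$mean_fst[g$gene_id == "g3"], 0.2)
  expect_equal(g$snp_fst[[which(g$gene_id == "g1")]], c(0.1, 0.3))

  # gene with no SNPs: missing mean, zero count, empty list
  empty <- gene_mean_fst(genes, fst[0, ])
  expect_true(all(is.na(empty$mean_fst)))
  expect_equal(empty$n_snps, c(0L, 0L, 0L))
  expect_equal(empty$snp_fst[[1]], numeric(0))
})

test_that("gene means match a brute-force loop and ignore SNP order", {
  set.seed(61)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    chrom = sample(c("c1", "c2"), 20, replace = TRUE),
    start = sample.int(5000, 20),
    strand = "+"
  ) |>
    dplyr::mutate(end = start + sample(100:500, 20, replace = TRUE))
  fst <- tibble::tibble(
    chrom = sample(c("c1", "c2"), 400, replace = TRUE),
    pos = sample.int(6000, 400, replace = TRUE),
    pool_a = "p1", pool_b = "p2",
    fst = runif(400, -0.05, 1)
  )
  g <- gene_mean_fst(genes, fst)
  # independent oracle: explicit containment loop
  for (i in seq_len(nrow(genes))) {
    inside <- fst$fst[fst$chrom == genes$chrom[i] &
                        fst$pos - 1 >= genes$start[i] &
                        fst$pos - 1 < genes$end[i]]
    row <- g[g$gene_id == genes$gene_id[i], ]
    expect_equal(row$n_snps, length(inside))
    if (length(inside)) expect_equal(row$mean_fst, mean(inside))
  }
  shuffled <- gene_mean_fst(genes, fst[sample.int(400), ])
  expect_equal(shuffled$mean_fst, g$mean_fst)
  expect_equal(shuffled$n_snps, g$n_snps)
})

test_that("genes inherit the window they overlap most, ties to the left", {
  windows <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 100L), end = c(100L, 200L),
    pool_id = "p1",
    he_bar = c(0.001, 0.002), n_snps = c(3L, 4L)
  )
  genes <- tibble::tibble(
    gene_id = c("inside", "mostly_left", "split_even"),
    chrom = "chr1",
    start = c(10L, 40L, 60L),
    end = c(50L, 140L, 140L), # 60/40 split; 40/40 split
    strand = "+"
  )
  a <- assign_window_he(genes, windows)
  expect_equal(a$he[a$gene_id == "inside"], 0.001)
  expect_equal(a$he[a$gene_id == "mostly_left"], 0.001) # 60 bp in left window
  expect_equal(a$he[a$gene_id == "split_even"], 0.001) # tie -> left window
  expect_equal(a$window_start[a$gene_id == "split_even"], 0L)

  # gene on a chromosome with no windows gets no assignment
  orphan <- tibble::tibble(gene_id = "gX", chrom = "chrZ",
                           start = 0L, end = 10L, strand = "+")
  expect_equal(nrow(assign_window_he(orphan, windows)), 0L)
})

test_that("ortholog filtering applies quality, multiplicity and overlap rules", {
  genes_a <- tibble::tibble(
    gene_id = c("a1", "a2", "a3", "a4", "a5", "a6"),
    chrom = "c1",
    start = c(0L, 100L, 200L, 300L, 400L, 450L),
    end = c(50L, 150L, 250L, 350L, 460L, 500L), # a5/a6 overlap
    strand = "+"
  )
  genes_b <- tibble::tibble(
    gene_id = paste0("b", 1:6),
    chrom = "c1",
    start = seq(0L, 500L, by = 100L),
    end = seq(0L, 500L, by = 100L) + 50L,
    strand = "+"
  )
  pairs <- tibble::tibble(
    gene_a = c("a1", "a2", "a3", "a3", "a5", "a6"),
    gene_b = c("b1", "b2", "b3", "b4", "b5", "b6"),
    mapping_quality = c(255, 255, 255, 255, 255, 255),
    percent_identity = c(99, 89.9, 95, 95, 95, 95),
    relation = c("one2one", "one2one", "one2many", "one2many",
                 "one2one", "one2one")
  )
  kept <- filter_orthologs(pairs, genes_a, genes_b)
  # a2: below 90% identity; a3: two surviving matches, both dropped;
  # a5/a6: overlapping intervals in species A
  expect_equal(kept$gene_a, "a1")
  expect_false(anyDuplicated(kept$gene_a) > 0)
  expect_false(anyDuplicated(kept$gene_b) > 0)
})

test_that("mapping quality below threshold removes a pair before multiplicity", {
  genes_a <- tibble::tibble(gene_id = c("a1"), chrom = "c1",
                            start = 0L, end = 50L, strand = "+")
  genes_b <- tibble::tibble(gene_id = c("b1", "b2"), chrom = "c1",
                            start = c(0L, 100L), end = c(50L, 150L), strand = "+")
  pairs <- tibble::tibble(
    gene_a = c("a1", "a1"),
    gene_b = c("b1", "b2"),
    mapping_quality = c(255, 79),
    percent_identity = c(95, 95),
    relation = "one2many"
  )
  # the low-mapq pair dies at the quality step, so a1-b1 is 1:1 afterwards
  kept <- filter_orthologs(pairs, genes_a, genes_b)
  expect_equal(kept$gene_b, "b1")
})

test_that("unresolvable gene ids are dropped with a warning", {
  genes_a <- tibble::tibble(gene_id = "a1", chrom = "c1",
                            start = 0L, end = 50L, strand = "+")
  genes_b <- tibble::tibble(gene_id = "b1", chrom = "c1",
                            start = 0L, end = 50L, strand = "+")
  pairs <- tibble::tibble(
    gene_a = c("a1", "aX"), gene_b = c("b1", "b1"),
    mapping_quality = 255, percent_identity = 95, relation = "one2one"
  )
  expect_warning(kept <- filter_orthologs(pairs, genes_a, genes_b), "not in annotation")
  expect_equal(kept$gene_a, "a1")
})
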