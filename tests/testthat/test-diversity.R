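meta <- two_pool_meta()

test_that("expected heterozygosity follows 2p(1-p)", {
  expect_equal(snp_he(0.5), 0.5)
  expect_equal(snp_he(c(0, 1)), c(0, 0))
  expect_equal(snp_he(0.1), 0.18)
  expect_true(is.na(snp_he(NA_real_)))
  expect_error(snp_he(1.2))
})

test_that("windowed heterozygosity divides by window length, not SNP count", {
  lens <- tibble::tibble(chrom = "chr1", length = 120000)
  # one pool: SNP at he 0.5 alone in window 1; two SNPs (0.5, 0.18) in window 2;
  # window 3 (partial, 20 kb) has one SNP at he 0.5
  freqs <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 60000L, 70000L, 110000L),
    pool_id = "p1", he = c(0.5, 0.5, 0.18, 0.5)
  )
  w <- windowed_he(freqs, lens, window_size = 50000L)
  expect_equal(nrow(w), 3L)
  expect_equal(w$he_bar[1], 1e-5)
  expect_equal(w$he_bar[2], 0.68 / 50000)
  # trailing partial window uses its actual 20-kb length
  expect_equal(w$end[3] - w$start[3], 20000L)
  expect_equal(w$he_bar[3], 0.5 / 20000)
})

test_that("windows with no SNPs score zero and SNPs beyond the tiling error", {
  lens <- tibble::tibble(chrom = "chr1", length = 100000)
  freqs <- tibble::tibble(chrom = "chr1", pos = 10L, pool_id = "p1", he = 0.2)
  w <- windowed_he(freqs, lens, window_size = 50000L)
  expect_equal(w$he_bar[2], 0)
  expect_equal(w$n_snps[2], 0L)

  bad <- tibble::tibble(chrom = "chr1", pos = 100001L, pool_id = "p1", he = 0.2)
  expect_error(windowed_he(bad, lens, window_size = 50000L), "beyond")
  bad2 <- tibble::tibble(chrom = "chrX", pos = 10L, pool_id = "p1", he = 0.2)
  expect_error(windowed_he(bad2, lens, window_size = 50000L), "chrX")
})

test_that("window totals conserve the per-SNP heterozygosity sum", {
  set.seed(31)
  for (i in 1:5) {
    len <- sample(5e4:5e5, 1)
    lens <- tibble::tibble(chrom = c("c1", "c2"), length = c(len, len * 2))
    freqs <- purrr::map_dfr(c("c1", "c2"), function(ch) {
      n <- sample(50:300, 1)
      L <- lens$length[lens$chrom == ch]
      tidyr::expand_grid(
        tibble::tibble(chrom = ch, pos = sample.int(L, n)),
        pool_id = c("p1", "p2")
      ) |>
        dplyr::mutate(he = snp_he(runif(dplyr::n(), 0, 0.5)))
    })
    w <- windowed_he(freqs, lens, window_size = 7500L)
    tot_w <- w |>
      dplyr::group_by(pool_id) |>
      dplyr::summarise(s = sum(he_bar * (end - start)))
    tot_s <- freqs |>
      dplyr::group_by(pool_id) |>
      dplyr::summarise(s = sum(he))
    expect_equal(tot_w$s, tot_s$s, tolerance = 1e-12)
  }
})

test_that("an optional callable-site mask replaces the window denominator", {
  lens <- tibble::tibble(chrom = "chr1", length = 50000)
  freqs <- tibble::tibble(chrom = "chr1", pos = 100L, pool_id = "p1", he = 0.5)
  mask <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L)
  w <- windowed_he(freqs, lens, window_size = 50000L, mask = mask)
  expect_equal(w$he_bar, 0.5 / 10000)
})

test_that("pool FST hits its closed-form landmarks", {
  # fixed opposite alleles at high depth -> 1 exactly
  v <- make_variants(meta, ref1 = 1000L, alt1 = 0L, ref2 = 0L, alt2 = 1000L)
  f <- snp_fst(v, meta)
  expect_equal(f$fst, 1)

  # identical deep profiles -> near 0 (slightly negative allowed)
  v2 <- make_variants(meta, ref1 = 600L, alt1 = 400L, ref2 = 600L, alt2 = 400L)
  f2 <- snp_fst(v2, meta)
  expect_lt(abs(f2$fst), 0.02)

  # both pools fixed for the same allele -> undefined
  v3 <- make_variants(meta, ref1 = 500L, alt1 = 0L, ref2 = 500L, alt2 = 0L)
  expect_true(is.na(snp_fst(v3, meta)$fst))

  # zero depth in one pool -> missing
  v4 <- make_variants(meta, ref1 = 0L, alt1 = 0L, ref2 = 50L, alt2 = 50L)
  expect_true(is.na(snp_fst(v4, meta)$fst))
})

test_that("Hudson cross-check estimator approaches its parametric limit", {
  d <- 1e6L
  v <- make_variants(meta,
                     ref1 = as.integer(0.8 * d), alt1 = as.integer(0.2 * d),
                     ref2 = as.integer(0.2 * d), alt2 = as.integer(0.8 * d))
  f <- snp_fst(v, meta, estimator = "hudson")
  expect_equal(f$fst, 0.36 / 0.68, tolerance = 1e-4)
})

test_that("pool-corrected estimator is depth-invariant where the naive one is not", {
  set.seed(41)
  ns <- 15000L
  p0 <- runif(ns, 0.05, 0.95)
  f_true <- 0.1
  p1 <- rbeta(ns, p0 * 9, (1 - p0) * 9) # (1-F)/F = 9
  p2 <- rbeta(ns, p0 * 9, (1 - p0) * 9)
  k1 <- rbinom(ns, 100L, p1)
  k2 <- rbinom(ns, 100L, p2)
  est_at_depth <- function(d) {
    c1 <- rpois(ns, d); c2 <- rpois(ns, d)
    r1 <- rbinom(ns, c1, k1 / 100); r2 <- rbinom(ns, c2, k2 / 100)
    v <- make_variants(meta, c1 - r1, r1, c2 - r2, r2)
    ph1 <- r1 / c1; ph2 <- r2 / c2
    naive <- ((ph1 - ph2)^2) / (ph1 * (1 - ph2) + ph2 * (1 - ph1))
    c(anova = genomewide_fst(snp_fst(v, meta))$fst,
      naive = mean(naive, na.rm = TRUE))
  }
  lo <- est_at_depth(20)
  hi <- est_at_depth(40)
  # doubling depth leaves the pool-aware estimate unchanged within MC error
  expect_lt(abs(lo[["anova"]] - hi[["anova"]]), 0.01)
  expect_equal(lo[["anova"]], f_true, tolerance = 0.02)
  # the plug-in read-frequency estimator is inflated at low depth
  expect_gt(lo[["naive"]] - hi[["naive"]], 0.01)
})

test_that("pool-aware and Hudson estimators agree when depth dwarfs pool size", {
  big_meta <- two_pool_meta(100L, 100L)
  v <- bn_counts(15000L, 0.1, big_meta, depth = 1000, seed = 43)
  m_anova <- mean(snp_fst(v, big_meta)$fst, na.rm = TRUE)
  m_hudson <- mean(snp_fst(v, big_meta, estimator = "hudson")$fst, na.rm = TRUE)
  expect_lt(abs(m_anova - m_hudson), 0.01)
})

test_that("genome-wide summaries report mean, SE and n", {
  s <- genomewide_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$se, 1 / sqrt(3))
  expect_equal(s$n, 3L)
  expect_equal(genomewide_summary(rep(4, 10))$se, 0)
  expect_true(is.na(genomewide_summary(5)$se))
  set.seed(51)
  x <- rnorm(1000)
  s2 <- genomewide_summary(x)
  expect_lt(abs(s2$mean), 3 * s2$se)
})

test_that("nearest-rank quantiles follow the ceiling(nq) rule", {
  expect_equal(quantile_threshold(1:10, 0.5), 5)
  expect_equal(quantile_threshold(10:1, 0.5), 5)
  expect_equal(quantile_threshold(1:1000, 0.999), 999)
  expect_equal(quantile_threshold(rep(7, 20), 0.99), 7)
  expect_equal(quantile_threshold(1:10, 0.05), 1)
  expect_error(quantile_threshold(numeric(0), 0.5), "non-missing")
})

test_that("north-south pairing covers all cross-latitude pool pairs", {
  m4 <- pool_meta(c("n1", "n2", "s1", "s2"), "ns", c(46L, 42L, 30L, 41L),
                  c("north", "north", "south", "south"))
  p <- north_south_pairs(m4)
  expect_equal(nrow(p), 4L)
  expect_setequal(paste(p$pool_a, p$pool_b),
                  c("n1 s1", "n1 s2", "n2 s1", "n2 s2"))
})
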