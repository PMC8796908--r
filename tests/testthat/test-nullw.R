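test_that("control-SNP draws are deterministic under a seed and warn when short", {
  fst <- tibble::tibble(chrom = "c1", pos = 1:500, pool_a = "a", pool_b = "b",
                        fst = runif(500))
  s1 <- draw_control_snps(fst, 100L, seed = 5)
  s2 <- draw_control_snps(fst, 100L, seed = 5)
  expect_identical(s1, s2)
  expect_equal(length(s1), 100L)
  s3 <- draw_control_snps(fst, 100L, seed = 6)
  expect_false(identical(s1, s3))
  expect_warning(all_of_them <- draw_control_snps(fst, 1000L, seed = 5),
                 "using all")
  expect_equal(length(all_of_them), 500L)
})

test_that("every SNP is drawn into the control set at the uniform rate", {
  vals <- 1:100 + 0.5
  hits <- numeric(100)
  for (s in 1:1000) {
    drawn <- draw_control_snps(vals, 10L, seed = s) - 0.5
    hits[drawn] <- hits[drawn] + 1
  }
  freq <- hits / 1000
  expect_true(all(abs(freq - 0.1) < 0.04))
})

test_that("W and Z match the closed forms on separated, tied and swapped samples", {
  wz <- wilcoxon_w_z(c(4, 5, 6), c(1, 2, 3))
  expect_equal(wz[["W"]], 9)
  expect_equal(wz[["Z"]], 4.5 / sqrt(5.25))
  expect_equal(wz[["Z"]], 1.9640, tolerance = 1e-4)

  same <- wilcoxon_w_z(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same[["W"]], 4.5) # n1 n2 / 2
  expect_equal(same[["Z"]], 0)

  a <- c(0.2, 0.5, 0.9, 0.4)
  b <- c(0.1, 0.5, 0.3)
  expect_equal(wilcoxon_w_z(a, b)[["Z"]], -wilcoxon_w_z(b, a)[["Z"]])
  expect_equal(wilcoxon_w_z(a, b)[["W"]] + wilcoxon_w_z(b, a)[["W"]],
               length(a) * length(b))

  all_tied <- wilcoxon_w_z(rep(1, 3), rep(1, 5))
  expect_equal(all_tied[["Z"]], 0)
})

test_that("Z equals exact permutation standardisation of U (small groups)", {
  perm_z <- function(x, y) {
    n1 <- length(x)
    pooled <- c(x, y)
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(length(pooled), n1)
    u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    # population moments over all equally likely assignments
    mu <- mean(u_all)
    sigma <- sqrt(mean((u_all - mu)^2))
    (u_obs - mu) / sigma
  }
  set.seed(81)
  for (i in 1:10) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- sample(seq(0, 1, by = 0.1), n1, replace = TRUE) # ties likely
    y <- sample(seq(0, 1, by = 0.1), n2, replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    expect_equal(wilcoxon_w_z(x, y)[["Z"]], perm_z(x, y), tolerance = 1e-12)
  }
})

# --- helpers to build a Null-W scenario directly at the gene level --------

nullw_inputs <- function(n_test = 3L, n_null = 999L, seed = 91) {
  set.seed(seed)
  mk_gene <- function(id, vals) {
    tibble::tibble(gene_id = id, chrom = "c1", start = 0L, end = 1L,
                   n_snps = length(vals), mean_fst = mean(vals),
                   snp_fst = list(vals))
  }
  test_ids <- sprintf("t%02d", seq_len(n_test))
  null_ids <- sprintf("n%03d", seq_len(n_null))
  genes_b <- dplyr::bind_rows(
    purrr::map(test_ids, ~ mk_gene(.x, runif(10, 0, 0.5))),
    purrr::map(null_ids, ~ mk_gene(.x, runif(10, 0, 0.5)))
  )
  orth <- tibble::tibble(
    gene_a = paste0("A_", c(test_ids, null_ids)),
    gene_b = c(test_ids, null_ids),
    mapping_quality = 255, percent_identity = 99, relation = "one2one"
  )
  cand <- tibble::tibble(
    gene_id = paste0("A_", c(test_ids, null_ids)),
    is_candidate = c(rep(TRUE, n_test), rep(FALSE, n_null))
  )
  fst_b <- tibble::tibble(chrom = "c1", pos = 1:5000, pool_a = "x", pool_b = "y",
                          fst = runif(5000, 0, 0.5))
  list(cand = cand, orth = orth, genes_b = genes_b, fst_b = fst_b)
}

test_that("a test gene beating every null gene gets empirical p = 1/(N+1)", {
  inp <- nullw_inputs(n_test = 1L, n_null = 999L)
  # make the single test gene's SNPs outrank everything
  inp$genes_b$snp_fst[[1]] <- rep(0.99, 10)
  inp$genes_b$mean_fst[1] <- 0.99
  nw <- null_w_test(inp$cand, inp$orth, inp$genes_b, inp$fst_b,
                    n_control = 2000L, seed = 3)
  expect_equal(nw$emp_p, 1 / 1000)
  expect_equal(length(attr(nw, "null_z")), 999L)

  gl <- glance(nw)
  expect_equal(gl$n_test_genes, 1L)
  expect_equal(gl$n_control_snps, 2000L)
})

test_that("a test gene matching the control distribution lands mid-pack", {
  inp <- nullw_inputs(n_test = 1L, n_null = 999L, seed = 95)
  # give the test gene SNP values at evenly spaced control quantiles: Z ~ 0,
  # so its empirical p sits near the centre of the null Z distribution
  inp$genes_b$snp_fst[[1]] <-
    unname(quantile(inp$fst_b$fst, probs = seq(0.05, 0.95, by = 0.1)))
  nw <- null_w_test(inp$cand, inp$orth, inp$genes_b, inp$fst_b,
                    n_control = 2000L, seed = 3)
  expect_lt(abs(nw$Z), 0.5)
  expect_gt(nw$emp_p, 0.3)
  expect_lt(nw$emp_p, 0.7)
})

test_that("a planted high-FST ortholog attains the smallest empirical p", {
  inp <- nullw_inputs(n_test = 5L, n_null = 300L, seed = 97)
  # plant gene t03: all SNP values in the top of the genome distribution
  i <- which(inp$genes_b$gene_id == "t03")
  inp$genes_b$snp_fst[[i]] <- runif(20, 0.45, 0.5)
  inp$genes_b$n_snps[i] <- 20L
  nw <- null_w_test(inp$cand, inp$orth, inp$genes_b, inp$fst_b,
                    n_control = 2000L, seed = 3)
  expect_equal(nw$gene_b[which.min(nw$emp_p)], "t03")
  expect_equal(min(nw$adj_p), min(nw$emp_p) * nrow(nw))
})

test_that("genes below the SNP floor are excluded and empty test sets warn", {
  inp <- nullw_inputs(n_test = 2L, n_null = 200L)
  inp$genes_b$n_snps[1] <- 0L
  inp$genes_b$snp_fst[[1]] <- numeric(0)
  nw <- null_w_test(inp$cand, inp$orth, inp$genes_b, inp$fst_b,
                    n_control = 1000L, seed = 3, min_snps_per_gene = 1L)
  expect_equal(nrow(nw), 1L)

  no_cand <- dplyr::mutate(inp$cand, is_candidate = FALSE)
  expect_warning(
    empty <- null_w_test(no_cand, inp$orth, inp$genes_b, inp$fst_b,
                         n_control = 1000L, seed = 3),
    "empty"
  )
  expect_equal(nrow(empty), 0L)
})

test_that("the random_k null-set option subsamples deterministically", {
  inp <- nullw_inputs(n_test = 2L, n_null = 400L)
  nw1 <- null_w_test(inp$cand, inp$orth, inp$genes_b, inp$fst_b,
                     n_control = 1000L, seed = 3,
                     null_gene_set = "random_k", n_null_genes = 150L)
  nw2 <- null_w_test(inp$cand, inp$orth, inp$genes_b, inp$fst_b,
                     n_control = 1000L, seed = 3,
                     null_gene_set = "random_k", n_null_genes = 150L)
  expect_equal(length(attr(nw1, "null_z")), 150L)
  expect_identical(nw1$emp_p, nw2$emp_p)
})

test_that("the Null-W plot renders", {
  inp <- nullw_inputs(n_test = 3L, n_null = 200L)
  nw <- null_w_test(inp$cand, inp$orth, inp$genes_b, inp$fst_b,
                    n_control = 500L, seed = 3)
  expect_s3_class(autoplot(nw), "ggplot")
})
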