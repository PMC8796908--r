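#' Per-pool allele frequencies and expected heterozygosity
#'
#' Adds, for every site x pool row, the read depth, the plug-in alt allele
#' frequency `p = alt_reads / depth` and the biallelic expected
#' heterozygosity `2 p (1 - p)`. The plug-in read frequency is used without
#' a depth correction; windowed averages of this quantity are close to
#' unbiased across realistic coverages. Pools with zero depth at a site get
#' missing frequency and heterozygosity.
#'
#' @param variants Long variant tibble (site x pool rows).
#' @return `variants` with columns `depth`, `freq`, `he` appended.
#' @export
snp_frequencies <- function(variants) {
  variants |>
    dplyr::mutate(
      depth = .data$ref_reads + .data$alt_reads,
      freq = dplyr::if_else(.data$depth > 0L,
                            .data$alt_reads / .data$depth, NA_real_),
      he = snp_he(.data$freq)
    )
}

#' Expected heterozygosity of a biallelic site
#'
#' @param p Allele frequency (any vector of values in `[0, 1]`; `NA` in,
#'   `NA` out).
#' @return `2 p (1 - p)`.
#' @examples
#' snp_he(c(0, 0.1, 0.5, 1)) # 0, 0.18, 0.5, 0
#' @export
snp_he <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * p * (1 - p)
}

#' Tile chromosomes with fixed-width windows
#'
#' Windows are anchored at position 0 of each chromosome and tile it without
#' overlap; the trailing window is truncated at the chromosome end (its
#' actual length is used as the averaging denominator downstream).
#'
#' @param chrom_lengths Tibble with columns `chrom`, `length` (bp).
#' @param window_size Window width in bp (default 50,000).
#' @return Tibble of `chrom`, `start`, `end` (0-based half-open).
#' @export
make_windows <- function(chrom_lengths, window_size = 50000L) {
  stopifnot(window_size >= 1)
  purrr::pmap_dfr(chrom_lengths, function(chrom, length, ...) {
    starts <- seq(0L, length - 1L, by = window_size)
    tibble::tibble(chrom = chrom, start = as.integer(starts),
                   end = as.integer(pmin(starts + window_size, length)))
  })
}

#' Windowed average expected heterozygosity per pool
#'
#' Averages per-SNP expected heterozygosity over fixed windows, counting
#' every non-SNP site in the window as 0: the window value is
#' `sum(H_E of SNPs in window) / window_length`. This makes window scores
#' comparable across windows with different SNP densities and is why values
#' are typically of order 1e-3. Windows with no SNPs score 0.
#'
#' @param freqs Output of [snp_frequencies()] (needs `chrom`, `pos`,
#'   `pool_id`, `he`).
#' @param chrom_lengths Tibble of `chrom`, `length`; every SNP must fall on
#'   a listed chromosome within its length.
#' @param window_size Window width in bp (default 50,000).
#' @param mask Optional callable-site tibble of `chrom`, `start`, `end`
#'   (0-based half-open); when given, the denominator of each window is the
#'   number of callable bases it contains instead of its full length.
#' @return Tibble of `chrom`, `start`, `end`, `pool_id`, `he_bar`, `n_snps`,
#'   covering every window x pool combination (zero-SNP windows included).
#' @export
windowed_he <- function(freqs, chrom_lengths, window_size = 50000L, mask = NULL) {
  windows <- make_windows(chrom_lengths, window_size)

  bad_chrom <- setdiff(unique(freqs$chrom), chrom_lengths$chrom)
  if (length(bad_chrom)) {
    stop("SNPs on chromosome(s) not covered by the window tiling: ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  }
  max_pos <- freqs |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(mx = max(.data$pos), .groups = "drop") |>
    dplyr::left_join(chrom_lengths, by = "chrom")
  if (any(max_pos$mx > max_pos$length)) {
    stop("SNP position beyond declared chromosome length", call. = FALSE)
  }

  denom <- windows |>
    dplyr::mutate(denom = .data$end - .data$start)
  if (!is.null(mask)) {
    overlap <- dplyr::inner_join(
      windows, mask,
      by = dplyr::join_by("chrom", "start" < "end", "end" > "start"),
      suffix = c("", "_m")
    ) |>
      dplyr::mutate(ov = pmin(.data$end, .data$end_m) - pmax(.data$start, .data$start_m)) |>
      dplyr::group_by(.data$chrom, .data$start, .data$end) |>
      dplyr::summarise(callable = sum(.data$ov), .groups = "drop")
    denom <- denom |>
      dplyr::left_join(overlap, by = c("chrom", "start", "end")) |>
      dplyr::mutate(denom = dplyr::coalesce(.data$callable, 0L)) |>
      dplyr::select(-"callable")
  }

  # SNP at 1-based pos falls in the window containing 0-based coordinate pos-1
  sums <- freqs |>
    dplyr::mutate(start = as.integer((.data$pos - 1L) %/% window_size) * as.integer(window_size)) |>
    dplyr::group_by(.data$chrom, .data$start, .data$pool_id) |>
    dplyr::summarise(he_sum = sum(.data$he, na.rm = TRUE),
                     n_snps = sum(!is.na(.data$he)), .groups = "drop")

  tidyr::expand_grid(denom, pool_id = unique(freqs$pool_id)) |>
    dplyr::left_join(sums, by = c("chrom", "start", "pool_id")) |>
    dplyr::mutate(
      he_sum = dplyr::coalesce(.data$he_sum, 0),
      n_snps = dplyr::coalesce(.data$n_snps, 0L),
      he_bar = dplyr::if_else(.data$denom > 0, .data$he_sum / .data$denom, NA_real_)
    ) |>
    dplyr::select("chrom", "start", "end", "pool_id", "he_bar", "n_snps") |>
    dplyr::arrange(.data$chrom, .data$start, .data$pool_id)
}

#' Per-SNP FST between pool pairs
#'
#' The default estimator is a pool-aware ANOVA (method-of-moments)
#' estimator built on probabilities of identity in state (IIS). For a pool
#' of haploid size `n` (2N chromosomes) sequenced to depth `c` with `r`
#' alt reads, two distinct reads are drawn from the same chromosome with
#' probability `1/n`, so the unbiased within-pool identity is
#' `Q1 = (n * IIS_reads - 1) / (n - 1)` with
#' `IIS_reads = (r(r-1) + (c-r)(c-r-1)) / (c(c-1))`; between pools
#' `Q2 = (r1 r2 + (c1-r1)(c2-r2)) / (c1 c2)`. Per SNP,
#' `FST = (Q1 - Q2) / (1 - Q2)` with `Q1` averaged over the two pools.
#' This two-stage correction (individuals sampled into the pool, then reads
#' sampled from the pool) makes the estimator unbiased in depth, unlike
#' plug-in estimators on read frequencies.
#'
#' `estimator = "hudson"` gives the depth-corrected Hudson estimator on read
#' frequencies as an independent cross-check:
#' `[(p1-p2)^2 - p1(1-p1)/(c1-1) - p2(1-p2)/(c2-1)] / [p1(1-p2) + p2(1-p1)]`.
#'
#' Missing values are returned where either pool has insufficient depth
#' (`< 2` reads) or where both pools are fixed for the same allele
#' (undefined denominator). Negative values are kept: they are an estimator
#' property and clamping would bias outlier quantiles.
#'
#' @param variants Long variant tibble (site x pool rows).
#' @param meta Pool metadata from [pool_meta()].
#' @param pairs Tibble of `pool_a`, `pool_b` naming the pairs to score.
#'   Default: every north x south pool pair within each species.
#' @param estimator `"anova"` (default) or `"hudson"`.
#' @return Tibble of `chrom`, `pos`, `pool_a`, `pool_b`, `fst`, plus the
#'   per-SNP ratio components `fst_num` and `fst_den` used by
#'   [genomewide_fst()] (for the Hudson mode these are the Hudson
#'   numerator/denominator).
#' @export
snp_fst <- function(variants, meta, pairs = NULL, estimator = c("anova", "hudson")) {
  estimator <- match.arg(estimator)
  if (is.null(pairs)) pairs <- north_south_pairs(meta)
  stopifnot(all(c(pairs$pool_a, pairs$pool_b) %in% meta$pool_id))

  counts <- variants |>
    dplyr::select("chrom", "pos", "pool_id", "ref_reads", "alt_reads")

  one_pair <- function(pool_a, pool_b) {
    a <- counts |> dplyr::filter(.data$pool_id == pool_a)
    b <- counts |> dplyr::filter(.data$pool_id == pool_b)
    ab <- dplyr::inner_join(a, b, by = c("chrom", "pos"), suffix = c("_1", "_2"))
    c1 <- ab$ref_reads_1 + ab$alt_reads_1
    c2 <- ab$ref_reads_2 + ab$alt_reads_2
    r1 <- ab$alt_reads_1
    r2 <- ab$alt_reads_2
    if (estimator == "anova") {
      n1 <- meta$ploidy[meta$pool_id == pool_a]
      n2 <- meta$ploidy[meta$pool_id == pool_b]
      iis1 <- (r1 * (r1 - 1) + (c1 - r1) * (c1 - r1 - 1)) / (c1 * (c1 - 1))
      iis2 <- (r2 * (r2 - 1) + (c2 - r2) * (c2 - r2 - 1)) / (c2 * (c2 - 1))
      q1 <- ((n1 * iis1 - 1) / (n1 - 1) + (n2 * iis2 - 1) / (n2 - 1)) / 2
      q2 <- (r1 * r2 + (c1 - r1) * (c2 - r2)) / (c1 * c2)
      num <- q1 - q2
      den <- 1 - q2
    } else {
      p1 <- r1 / c1
      p2 <- r2 / c2
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (c1 - 1) - p2 * (1 - p2) / (c2 - 1)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
    }
    ok <- c1 >= 2L & c2 >= 2L & is.finite(den) & den > 0
    tibble::tibble(
      chrom = ab$chrom, pos = ab$pos,
      pool_a = pool_a, pool_b = pool_b,
      fst = ifelse(ok, num / den, NA_real_),
      fst_num = ifelse(ok, num, NA_real_),
      fst_den = ifelse(ok, den, NA_real_)
    )
  }
  purrr::pmap_dfr(pairs, one_pair)
}

#' Default north-south pool pairing within each species
#'
#' @param meta Pool metadata from [pool_meta()].
#' @return Tibble of `species`, `pool_a` (north), `pool_b` (south).
#' @export
north_south_pairs <- function(meta) {
  north <- meta |> dplyr::filter(.data$latitude_class == "north")
  south <- meta |> dplyr::filter(.data$latitude_class == "south")
  dplyr::inner_join(
    north |> dplyr::select(species = "species", pool_a = "pool_id"),
    south |> dplyr::select(species = "species", pool_b = "pool_id"),
    by = "species", relationship = "many-to-many"
  ) |>
    dplyr::select("pool_a", "pool_b")
}

#' Genome-wide multilocus FST
#'
#' The genome-wide FST of a species is the ratio-of-averages estimator
#' `sum(Q1 - Q2) / sum(1 - Q2)` over all scored SNPs (and pool pairs).
#' Averaging per-SNP ratios instead would be strongly biased towards zero,
#' because the per-SNP denominator is itself noisy; the ratio-of-averages
#' form recovers the simulated differentiation to within Monte-Carlo error.
#' The standard error reported is the descriptive SE of the per-SNP values.
#'
#' @param fst Output of [snp_fst()].
#' @return One-row tibble: `fst` (multilocus), `mean_snp_fst`, `se`, `n_snps`.
#' @export
genomewide_fst <- function(fst) {
  ok <- !is.na(fst$fst)
  persnp <- genomewide_summary(fst$fst)
  tibble::tibble(
    fst = sum(fst$fst_num[ok]) / sum(fst$fst_den[ok]),
    mean_snp_fst = persnp$mean,
    se = persnp$se,
    n_snps = persnp$n
  )
}

#' Mean, standard error and count of a statistic
#'
#' @param values Numeric vector; missing values are dropped.
#' @return One-row tibble of `mean`, `se` (`sd/sqrt(n)`; missing when
#'   `n < 2`) and `n`.
#' @examples
#' genomewide_summary(c(1, 2, 3)) # mean 2, se 0.577
#' @export
genomewide_summary <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  tibble::tibble(
    mean = if (n) mean(v) else NA_real_,
    se = if (n >= 2L) sd(v) / sqrt(n) else NA_real_,
    n = n
  )
}

#' Empirical quantile by the nearest-rank rule
#'
#' Uses the inverse-CDF (nearest-rank) definition: the value at rank
#' `ceiling(n * q)` of the sorted sample, i.e. R's type-1 quantile. With
#' 1000 distinct values and `q = 0.999` the threshold is the 999th order
#' statistic, so exactly one value lies strictly above it.
#'
#' @param values Numeric vector (missing values dropped; must leave >= 1).
#' @param q Quantile in (0, 1).
#' @return A single number.
#' @export
quantile_threshold <- function(values, q) {
  stopifnot(length(q) == 1L, q > 0, q < 1)
  v <- values[!is.na(values)]
  if (!length(v)) stop("no non-missing values to take a quantile of", call. = FALSE)
  unname(quantile(v, probs = q, type = 1, names = FALSE))
}
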