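#' Configuration for the synthetic Pool-seq generator
#'
#' Describes one simulated species: its genome layout, SNP count, pooled
#' sampling design and differentiation model. Population allele frequencies
#' follow the Balding-Nichols model: for a SNP with ancestral frequency
#' `p0 ~ Uniform(0.05, 0.95)`, each population draws its frequency from
#' `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`, so that the across-population
#' variance is `F p0 (1 - p0)`. `F` is `baseline_fst` genome-wide and
#' `elevated_fst` for SNPs inside selected genes. Pool read counts are then
#' produced by two-stage sampling: `2N` allele copies binomially from the
#' population frequency, then reads binomially from the pool allele
#' fraction at a Poisson depth — the same two layers of noise real
#' Pool-seq data carries, and the reason a pool-aware FST estimator is
#' needed.
#'
#' The default pooled design mirrors the sequenced populations this
#' generator emulates: two pools of ~50 diploids per species at a target
#' depth of 2N reads, one pool per side of a north/south contrast, with
#' genome-wide baseline differentiation of order 0.1 (see [sim_preset()]
#' for the three named species presets).
#'
#' @param species Species label; used as prefix for gene and pool ids.
#' @param n_chromosomes,chromosome_length Genome layout (bp per chromosome).
#' @param n_genes,gene_length Genes are placed without overlap, evenly
#'   spaced with jitter, and split across chromosomes.
#' @param n_snps Total SNP count, split across chromosomes by length.
#' @param pools Tibble with one row per pool: `n_individuals`,
#'   `target_depth`, `latitude_class` (and optionally `pool_id`).
#' @param baseline_fst Genome-wide Balding-Nichols `F`.
#' @param n_selected Number of genes planted under divergent selection.
#' @param elevated_fst `F` for SNPs inside selected genes; must exceed
#'   `baseline_fst`.
#' @param qual_range Range of simulated site QUAL values (uniform).
#' @param seed Integer seed (mandatory; the generator is deterministic).
#' @return A list of class `poolscan_sim_config`.
#' @export
sim_config <- function(species = "speciesA",
                       n_chromosomes = 2L, chromosome_length = 2.5e6,
                       n_genes = 200L, gene_length = 2000L,
                       n_snps = 10000L,
                       pools = NULL,
                       baseline_fst = 0.14, n_selected = 0L,
                       elevated_fst = 0.6,
                       qual_range = c(15, 60),
                       seed = 1L) {
  if (is.null(pools)) {
    pools <- tibble::tibble(
      n_individuals = c(50L, 50L),
      target_depth = c(100, 100),
      latitude_class = c("north", "south")
    )
  }
  if (!"pool_id" %in% names(pools)) {
    pools$pool_id <- sprintf("%s_p%d", species, seq_len(nrow(pools)))
  }
  stopifnot(baseline_fst > 0, baseline_fst < 1,
            elevated_fst > baseline_fst, elevated_fst < 1,
            n_selected <= n_genes, !is.null(seed))
  structure(
    list(species = species, n_chromosomes = as.integer(n_chromosomes),
         chromosome_length = chromosome_length, n_genes = as.integer(n_genes),
         gene_length = as.integer(gene_length), n_snps = as.integer(n_snps),
         pools = pools, baseline_fst = baseline_fst,
         n_selected = as.integer(n_selected), elevated_fst = elevated_fst,
         qual_range = qual_range, seed = as.integer(seed)),
    class = "poolscan_sim_config"
  )
}

#' Named species presets for the generator
#'
#' Three qualitative regimes of genetic diversity observed across the
#' stickleback order, at desk scale: `"threespine"` (two pools of 52/51
#' diploids, baseline FST 0.14), `"tubesnout"` (44/50 diploids, FST 0.12)
#' and `"ninespine"` (a bottlenecked, strongly drifted species: four pools
#' of 46/42/30/41 diploids, FST 0.49). Target depth is twice the pool size
#' (one read per chromosome in expectation), matching the sequencing
#' design the generator emulates.
#'
#' @param preset One of `"threespine"`, `"tubesnout"`, `"ninespine"`.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `poolscan_sim_config`.
#' @export
sim_preset <- function(preset = c("threespine", "tubesnout", "ninespine"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    threespine = list(
      species = "threespine", baseline_fst = 0.14,
      pools = tibble::tibble(
        pool_id = c("TsN", "TsS"),
        n_individuals = c(52L, 51L),
        target_depth = c(104, 102),
        latitude_class = c("north", "south")
      )
    ),
    tubesnout = list(
      species = "tubesnout", baseline_fst = 0.12,
      pools = tibble::tibble(
        pool_id = c("TuN", "TuS"),
        n_individuals = c(44L, 50L),
        target_depth = c(88, 100),
        latitude_class = c("north", "south")
      )
    ),
    ninespine = list(
      species = "ninespine", baseline_fst = 0.49,
      pools = tibble::tibble(
        pool_id = c("NsN1", "NsN2", "NsS1", "NsS2"),
        n_individuals = c(46L, 42L, 30L, 41L),
        target_depth = c(92, 84, 60, 82),
        latitude_class = c("north", "north", "south", "south")
      )
    )
  )
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# non-overlapping gene placement: equal slots per chromosome, jittered
place_genes <- function(cfg) {
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1)))
  purrr::map_dfr(seq_len(cfg$n_chromosomes), function(ci) {
    ng <- per_chrom[ci]
    if (!ng) return(NULL)
    slot <- cfg$chromosome_length / ng
    if (slot < cfg$gene_length) {
      stop("gene placement exceeds chromosome length: ", ng, " genes of ",
           cfg$gene_length, " bp do not fit in ", cfg$chromosome_length,
           " bp", call. = FALSE)
    }
    jitter <- floor(runif(ng, 0, slot - cfg$gene_length))
    start <- as.integer(floor((seq_len(ng) - 1) * slot) + jitter)
    tibble::tibble(
      chrom = paste0("chr", ci),
      start = start,
      end = start + cfg$gene_length,
      strand = sample(c("+", "-"), ng, replace = TRUE)
    )
  }) |>
    dplyr::mutate(gene_id = sprintf("%s_g%04d", cfg$species, dplyr::row_number())) |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand")
}

#' Simulate one species' pooled variant data
#'
#' Generates the full data bundle for one species under the model described
#' in [sim_config()]: a long site x pool count table (same shape as
#' [read_pooled_vcf()] output), the pool metadata, non-overlapping gene
#' annotations, chromosome lengths, and truth tables recording every
#' simulated quantity (ancestral and per-population allele frequencies,
#' the `F` each SNP was drawn under, and per-gene selection labels).
#' Identical configs (including seed) give identical output.
#'
#' @param cfg A [sim_config()] or [sim_preset()].
#' @param selected_ids Optional character vector naming the genes to plant
#'   under selection (overrides `cfg$n_selected`); used by
#'   [simulate_species_pair()] to coordinate convergent genes.
#' @return A list of class `poolscan_sim`: `variants`, `meta`, `genes`,
#'   `chrom_lengths`, `truth_snps` (site level: `chrom`, `pos`, `p0`,
#'   `f_snp`, `gene_id`, `selected`), `truth_freqs` (site x pool true
#'   frequencies) and `truth_genes` (`gene_id`, `selected`).
#' @export
simulate_species <- function(cfg, selected_ids = NULL) {
  stopifnot(inherits(cfg, "poolscan_sim_config"))
  withr_seed(cfg$seed, simulate_species_impl(cfg, selected_ids))
}

simulate_species_impl <- function(cfg, selected_ids) {
  chrom_lengths <- tibble::tibble(
    chrom = paste0("chr", seq_len(cfg$n_chromosomes)),
    length = cfg$chromosome_length
  )
  genes <- place_genes(cfg)
  if (is.null(selected_ids)) {
    selected_ids <- if (cfg$n_selected > 0L) {
      sample(genes$gene_id, cfg$n_selected)
    } else character(0)
  }
  stopifnot(all(selected_ids %in% genes$gene_id))

  # SNP positions, split across chromosomes by length
  per_chrom <- diff(round(seq(0, cfg$n_snps, length.out = cfg$n_chromosomes + 1)))
  sites <- purrr::map_dfr(seq_len(cfg$n_chromosomes), function(ci) {
    tibble::tibble(
      chrom = paste0("chr", ci),
      pos = sort(sample.int(cfg$chromosome_length, per_chrom[ci]))
    )
  })
  n <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  sites <- sites |>
    dplyr::mutate(ref = ref, alt = unname(alt),
                  qual = round(runif(n, cfg$qual_range[1], cfg$qual_range[2]), 1),
                  n_alt = 1L)

  # which SNPs sit in a (selected) gene
  sel_genes <- genes |> dplyr::filter(.data$gene_id %in% selected_ids)
  site_gene <- dplyr::left_join(
    sites |> dplyr::mutate(pos0 = .data$pos - 1L),
    genes |> dplyr::select("gene_id", "chrom", "start", "end"),
    by = dplyr::join_by("chrom", "pos0" >= "start", "pos0" < "end")
  )
  sites$gene_id <- site_gene$gene_id
  sites$selected <- !is.na(sites$gene_id) & sites$gene_id %in% selected_ids

  p0 <- runif(n, 0.05, 0.95)
  f_snp <- ifelse(sites$selected, cfg$elevated_fst, cfg$baseline_fst)

  truth_snps <- sites |>
    dplyr::mutate(p0 = p0, f_snp = f_snp) |>
    dplyr::select("chrom", "pos", "p0", "f_snp", "gene_id", "selected")

  meta <- pool_meta(cfg$pools$pool_id, cfg$species,
                    cfg$pools$n_individuals, cfg$pools$latitude_class)

  sim_pool <- function(pool_id, n_individuals, target_depth, ...) {
    ploidy <- 2L * n_individuals
    shape_ok <- f_snp > 1e-9
    p_pop <- p0
    if (any(shape_ok)) {
      a <- p0 * (1 - f_snp) / f_snp
      b <- (1 - p0) * (1 - f_snp) / f_snp
      p_pop[shape_ok] <- rbeta(sum(shape_ok), a[shape_ok], b[shape_ok])
    }
    copies <- rbinom(n, ploidy, p_pop)
    depth <- rpois(n, target_depth)
    alt_reads <- rbinom(n, depth, copies / ploidy)
    tibble::tibble(
      chrom = sites$chrom, pos = sites$pos,
      pool_id = pool_id,
      ref_reads = depth - alt_reads, alt_reads = alt_reads,
      p_true = p_pop
    )
  }
  counts <- purrr::pmap_dfr(cfg$pools, sim_pool)

  variants <- counts |>
    dplyr::inner_join(sites |> dplyr::select("chrom", "pos", "ref", "alt",
                                             "qual", "n_alt"),
                      by = c("chrom", "pos")) |>
    dplyr::select("chrom", "pos", "ref", "alt", "qual", "n_alt",
                  "pool_id", "ref_reads", "alt_reads") |>
    dplyr::arrange(.data$chrom, .data$pos, match(.data$pool_id, meta$pool_id))

  structure(
    list(
      variants = variants,
      meta = meta,
      genes = genes,
      chrom_lengths = chrom_lengths,
      truth_snps = truth_snps,
      truth_freqs = counts |> dplyr::select("chrom", "pos", "pool_id", "p_true"),
      truth_genes = genes |>
        dplyr::transmute(gene_id = .data$gene_id,
                         selected = .data$gene_id %in% selected_ids),
      config = cfg
    ),
    class = "poolscan_sim"
  )
}

#' Simulate a species pair with a shared ortholog map
#'
#' Builds two species datasets plus the ortholog table connecting them.
#' Both species get the same gene count; gene `i` of A is the ortholog of
#' gene `i` of B. A configurable fraction of A genes additionally map to a
#' second B gene (yielding `one2many` relations, which the downstream
#' filter must remove); alignment identity is Normal(`identity_mean`,
#' `identity_sd`) truncated to `[0, 100]` and a fraction of pairs get low
#' mapping quality, so some pairs fail the quality filter. Convergent
#' genes — planted under elevated `F` in BOTH species — are drawn only from
#' pairs that survive all ortholog filters (otherwise they could never be
#' tested). Species-specific selection (`n_selected` in each config) is
#' planted on top, disjoint from the convergent set in the other species.
#'
#' @param cfg_a,cfg_b Configs from [sim_config()]; must have equal
#'   `n_genes`.
#' @param convergent_fraction Fraction of filter-surviving 1:1 ortholog
#'   pairs planted as convergent (selected in both species).
#' @param one2many_fraction Fraction of A genes with a second B match.
#' @param identity_mean,identity_sd Percent-identity distribution.
#' @param low_mapq_fraction Fraction of pairs assigned mapping quality 40
#'   (fails the default `min_mapq = 80`); the rest get 255.
#' @param seed Integer seed for the map and the planted-gene draws (the
#'   two species use their own config seeds).
#' @return A list of class `poolscan_sim_pair`: `sim_a`, `sim_b`,
#'   `orthologs` and `truth_orthologs` (the map plus logical columns
#'   `passes_filter` and `convergent`).
#' @export
simulate_species_pair <- function(cfg_a, cfg_b, convergent_fraction = 0,
                                  one2many_fraction = 0.1,
                                  identity_mean = 95, identity_sd = 3,
                                  low_mapq_fraction = 0.05, seed = 1L) {
  stopifnot(cfg_a$n_genes == cfg_b$n_genes,
            convergent_fraction >= 0, convergent_fraction <= 1)
  # gene placement must be known before counts are simulated, so build both
  # catalogues first (deterministic under each config's seed)
  genes_a <- withr_seed(cfg_a$seed, place_genes(cfg_a))
  genes_b <- withr_seed(cfg_b$seed, place_genes(cfg_b))

  map <- withr_seed(seed, {
    ng <- cfg_a$n_genes
    base <- tibble::tibble(
      gene_a = genes_a$gene_id,
      gene_b = genes_b$gene_id,
      relation = "one2one"
    )
    extra_idx <- which(runif(ng) < one2many_fraction)
    extra <- NULL
    if (length(extra_idx)) {
      partner <- vapply(extra_idx, function(i) {
        sample(setdiff(seq_len(ng), i), 1L)
      }, integer(1))
      extra <- tibble::tibble(
        gene_a = genes_a$gene_id[extra_idx],
        gene_b = genes_b$gene_id[partner],
        relation = "one2many"
      )
      base$relation[base$gene_a %in% extra$gene_a |
                      base$gene_b %in% extra$gene_b] <- "one2many"
    }
    pairs <- dplyr::bind_rows(base, extra)
    np <- nrow(pairs)
    pairs$percent_identity <- pmin(100, pmax(0, stats::rnorm(np, identity_mean, identity_sd)))
    pairs$mapping_quality <- ifelse(runif(np) < low_mapq_fraction, 40, 255)
    pairs
  })

  surviving <- filter_orthologs(map, genes_a, genes_b)
  n_conv <- round(convergent_fraction * nrow(surviving))
  if (convergent_fraction > 0 && n_conv > nrow(surviving)) {
    stop("convergent_fraction exceeds the fraction of clean 1:1 orthologs",
         call. = FALSE)
  }
  conv <- if (n_conv > 0L) {
    withr_seed(seed + 1L, surviving[sample.int(nrow(surviving), n_conv), ])
  } else {
    surviving[0, ]
  }

  pick_extra <- function(cfg, genes, exclude, seed_off) {
    if (cfg$n_selected <= 0L) return(character(0))
    pool <- setdiff(genes$gene_id, exclude)
    withr_seed(seed + seed_off, sample(pool, min(cfg$n_selected, length(pool))))
  }
  sel_a <- union(conv$gene_a, pick_extra(cfg_a, genes_a, conv$gene_a, 2L))
  sel_b <- union(conv$gene_b, pick_extra(cfg_b, genes_b, conv$gene_b, 3L))

  sim_a <- simulate_species(cfg_a, selected_ids = sel_a)
  sim_b <- simulate_species(cfg_b, selected_ids = sel_b)

  truth <- map |>
    dplyr::mutate(
      passes_filter = paste(.data$gene_a, .data$gene_b) %in%
        paste(surviving$gene_a, surviving$gene_b),
      convergent = paste(.data$gene_a, .data$gene_b) %in%
        paste(conv$gene_a, conv$gene_b)
    )
  structure(
    list(sim_a = sim_a, sim_b = sim_b,
         orthologs = map, truth_orthologs = truth),
    class = "poolscan_sim_pair"
  )
}

#' Write a simulated dataset to standard files
#'
#' Emits VCFv4.2 (per-pool `DP:AD` depths, `AD = ref,alt`), GFF3 gene
#' annotations, pool metadata TSV and the truth tables. The VCF
#' round-trips exactly through [read_pooled_vcf()].
#'
#' @param sim A `poolscan_sim` from [simulate_species()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; default the species label.
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, prefix = sim$config$species) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    gff = file.path(dir, paste0(prefix, ".gff3")),
    meta = file.path(dir, paste0(prefix, "_meta.tsv")),
    truth_snps = file.path(dir, paste0(prefix, "_truth_snps.tsv")),
    truth_genes = file.path(dir, paste0(prefix, "_truth_genes.tsv"))
  )
  write_sim_vcf(sim, paths["vcf"])
  write_sim_gff(sim$genes, paths["gff"])
  readr::write_tsv(sim$meta, paths["meta"])
  readr::write_tsv(sim$truth_snps, paths["truth_snps"])
  readr::write_tsv(sim$truth_genes, paths["truth_genes"])
  invisible(paths)
}

write_sim_vcf <- function(sim, path) {
  meta <- sim$meta
  sites <- sim$variants |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$qual)
  wide <- sim$variants |>
    dplyr::mutate(fmt = sprintf("%d:%d,%d", .data$ref_reads + .data$alt_reads,
                                .data$ref_reads, .data$alt_reads)) |>
    dplyr::select("chrom", "pos", "pool_id", "fmt") |>
    tidyr::pivot_wider(names_from = "pool_id", values_from = "fmt")
  tab <- dplyr::inner_join(sites, wide, by = c("chrom", "pos"))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=poolscan_simulate_v", packageVersion("poolscan")),
    sprintf("##contig=<ID=%s,length=%d>", sim$chrom_lengths$chrom,
            as.integer(sim$chrom_lengths$length)),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", meta$pool_id), collapse = "\t")
  )
  body <- do.call(paste, c(
    list(tab$chrom, tab$pos, ".", tab$ref, tab$alt, tab$qual, "PASS", ".",
         "DP:AD"),
    as.list(tab[meta$pool_id]),
    sep = "\t"
  ))
  writeLines(c(header, body), path)
  invisible(path)
}

write_sim_gff <- function(genes, path) {
  lines <- sprintf("%s\tpoolscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, genes$start + 1L, genes$end, genes$strand,
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write the ortholog table of a simulated pair
#'
#' @param pair A `poolscan_sim_pair`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sim_orthologs <- function(pair, path) {
  readr::write_tsv(
    pair$orthologs[, c("gene_a", "gene_b", "mapping_quality",
                       "percent_identity", "relation")],
    path
  )
  invisible(path)
}
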