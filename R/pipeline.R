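#' Run the full comparative genome-scan pipeline from one config
#'
#' Orchestrates every stage for a two-species comparison: data (either a
#' simulated pair or files on disk), SNP filtering, windowed
#' heterozygosity, per-SNP FST, gene-level aggregation, ortholog filtering,
#' the top-candidate scan in each species, the Null-W convergence test in
#' both directions, and the cross-species correlation/overlap summaries.
#' Every output table carries a provenance comment line; a `manifest.json`
#' records the package version, the config, the seed and per-stage counts.
#' All randomness derives from the single config seed, so a rerun with the
#' same config reproduces every table byte-identically (the manifest
#' differs only in its `created` timestamp).
#'
#' The config is a YAML file or an equivalent named list with top-level
#' keys: `seed`; either `simulate` (keys `preset_a`, `preset_b`, optional
#' overrides `n_snps`, `n_genes`, `n_chromosomes`, `chromosome_length`,
#' `gene_length`, `n_selected_a`, `n_selected_b`, `elevated_fst`,
#' `convergent_fraction`, `one2many_fraction`) or `inputs` (paths `vcf_a`,
#' `gff_a`, `meta_a`, `vcf_b`, `gff_b`, `meta_b`, `orthologs`); and
#' optional blocks `filters` ([filter_config()] arguments), `window_size`,
#' `outlier_quantile`, `p_success`, `ortholog_filter` (`min_mapq`,
#' `min_identity`) and `nullw` (`n_control`, `alpha`, `min_snps_per_gene`).
#'
#' @param config Path to a YAML config, or a named list.
#' @param out_dir Output directory (created if needed); overrides the
#'   config's `out_dir`.
#' @return Invisibly, a list with the in-memory results (`candidates_a`,
#'   `candidates_b`, `nullw_ab`, `nullw_ba`, `correlations`, `he_matrix`,
#'   `manifest`, ...).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)

  window_size <- as.integer(cfg$window_size %||% 50000L)
  outlier_q <- cfg$outlier_quantile %||% 0.999
  p_success <- cfg$p_success %||% 0.001
  fcfg <- do.call(filter_config, cfg$filters %||% list())
  ocfg <- cfg$ortholog_filter %||% list()
  ncfg <- cfg$nullw %||% list()

  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- data stage -----------------------------------------------------
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    ov <- s[intersect(names(s), c("n_snps", "n_genes", "n_chromosomes",
                                  "chromosome_length", "gene_length",
                                  "elevated_fst"))]
    cfg_a <- do.call(sim_preset, c(list(preset = s$preset_a %||% "threespine",
                                        seed = seed,
                                        n_selected = s$n_selected_a %||% 0L), ov))
    cfg_b <- do.call(sim_preset, c(list(preset = s$preset_b %||% "tubesnout",
                                        seed = seed + 1L,
                                        n_selected = s$n_selected_b %||% 0L), ov))
    pair <- stage("simulate", simulate_species_pair(
      cfg_a, cfg_b,
      convergent_fraction = s$convergent_fraction %||% 0,
      one2many_fraction = s$one2many_fraction %||% 0.1,
      seed = seed + 2L
    ))
    data_a <- pair$sim_a[c("variants", "meta", "genes", "chrom_lengths")]
    data_b <- pair$sim_b[c("variants", "meta", "genes", "chrom_lengths")]
    orth_raw <- pair$orthologs
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    load_species <- function(vcf, gff, meta_path) {
      meta_tab <- readr::read_tsv(meta_path, show_col_types = FALSE)
      meta <- pool_meta(meta_tab$pool_id, meta_tab$species,
                       meta_tab$n_individuals, meta_tab$latitude_class)
      genes <- read_gff_genes(gff)
      variants <- read_pooled_vcf(vcf, meta)
      chrom_lengths <- variants |>
        dplyr::group_by(chrom = .data$chrom) |>
        dplyr::summarise(length = max(.data$pos), .groups = "drop")
      list(variants = variants, meta = meta, genes = genes,
           chrom_lengths = chrom_lengths)
    }
    data_a <- stage("ingest_a", load_species(inp$vcf_a, inp$gff_a, inp$meta_a))
    data_b <- stage("ingest_b", load_species(inp$vcf_b, inp$gff_b, inp$meta_b))
    orth_raw <- stage("ingest_orthologs", read_ortholog_table(inp$orthologs))
  } else {
    stop("config must contain a 'simulate' or an 'inputs' block", call. = FALSE)
  }

  # ---- per-species stages --------------------------------------------
  run_species <- function(data, label) {
    filtered <- stage(paste0("filter_", label),
                      filter_variants(data$variants, fcfg))
    rep <- filter_report(filtered)
    counts[[paste0("filter_", label)]] <<- stats::setNames(
      as.list(rep$n_sites), rep$rule)
    freqs <- snp_frequencies(filtered)
    windows <- stage(paste0("windows_", label),
                     windowed_he(freqs, data$chrom_lengths, window_size))
    fst <- stage(paste0("fst_", label), snp_fst(filtered, data$meta))
    genes_fst <- gene_mean_fst(data$genes, fst)
    gene_he <- assign_window_he(data$genes, windows)
    flags <- fst_outlier_flags(fst, outlier_q)
    cands <- top_candidates(data$genes, flags, p_success = p_success)
    counts[[paste0("candidates_", label)]] <<- sum(cands$is_candidate)

    write_results_tsv(windows, file.path(out_dir, paste0("windows_", label, ".tsv")),
                      list(window_size = window_size))
    write_results_tsv(fst |> dplyr::select(-"fst_num", -"fst_den"),
                      file.path(out_dir, paste0("fst_", label, ".tsv")),
                      list(estimator = "anova"))
    write_results_tsv(genes_fst |> dplyr::select(-"snp_fst"),
                      file.path(out_dir, paste0("genes_", label, ".tsv")),
                      list())
    write_results_tsv(tidy(cands), file.path(out_dir, paste0("candidates_", label, ".tsv")),
                      list(q = outlier_q, p_success = p_success))
    write_results_tsv(rep, file.path(out_dir, paste0("filter_report_", label, ".tsv")),
                      list())
    list(filtered = filtered, windows = windows, fst = fst,
         genes_fst = genes_fst, gene_he = gene_he, candidates = cands,
         meta = data$meta, genes = data$genes)
  }
  res_a <- run_species(data_a, "a")
  res_b <- run_species(data_b, "b")
  sp_a <- res_a$meta$species[1]
  sp_b <- res_b$meta$species[1]

  # ---- orthologs & convergence ---------------------------------------
  orth <- stage("filter_orthologs", filter_orthologs(
    orth_raw, res_a$genes, res_b$genes,
    min_mapq = ocfg$min_mapq %||% 80,
    min_identity = ocfg$min_identity %||% 90
  ))
  counts$orthologs_in <- nrow(orth_raw)
  counts$orthologs_kept <- nrow(orth)
  write_results_tsv(orth, file.path(out_dir, "orthologs_filtered.tsv"), list())

  orth_rev <- orth |> dplyr::rename(gene_a = "gene_b", gene_b = "gene_a")
  nullw_ab <- stage("nullw_ab", null_w_test(
    res_a$candidates, orth, res_b$genes_fst, res_b$fst,
    n_control = ncfg$n_control %||% 10000L,
    min_snps_per_gene = ncfg$min_snps_per_gene %||% 1L,
    seed = seed + 10L, alpha = ncfg$alpha %||% 0.05
  ))
  nullw_ba <- stage("nullw_ba", null_w_test(
    res_b$candidates, orth_rev, res_a$genes_fst, res_a$fst,
    n_control = ncfg$n_control %||% 10000L,
    min_snps_per_gene = ncfg$min_snps_per_gene %||% 1L,
    seed = seed + 11L, alpha = ncfg$alpha %||% 0.05
  ))
  write_results_tsv(tidy(nullw_ab), file.path(out_dir, "nullw_a_to_b.tsv"),
                    list(direction = paste0(sp_a, "->", sp_b)))
  write_results_tsv(tidy(nullw_ba), file.path(out_dir, "nullw_b_to_a.tsv"),
                    list(direction = paste0(sp_b, "->", sp_a)))
  counts$nullw_ab_significant <- sum(nullw_ab$significant)
  counts$nullw_ba_significant <- sum(nullw_ba$significant)

  # ---- cross-species comparison --------------------------------------
  he_gene_mean <- function(gene_he) {
    gene_he |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(he = mean(.data$he), .groups = "drop")
  }
  fst_tab <- ortholog_score_table(res_a$genes_fst, res_b$genes_fst, orth, "mean_fst")
  he_tab <- ortholog_score_table(he_gene_mean(res_a$gene_he),
                                 he_gene_mean(res_b$gene_he), orth, "he")
  correlations <- dplyr::bind_rows(
    spearman_gene_correlation(fst_tab) |> dplyr::mutate(metric = "fst"),
    spearman_gene_correlation(he_tab) |> dplyr::mutate(metric = "he")
  ) |>
    dplyr::mutate(comparison = paste(sp_a, "vs", sp_b)) |>
    dplyr::select("comparison", "metric", "rho", "p_value", "n_genes")
  overlap <- extreme_overlap(he_tab)
  write_results_tsv(correlations, file.path(out_dir, "correlations.tsv"), list())
  write_results_tsv(overlap, file.path(out_dir, "extreme_overlap.tsv"), list())

  windows_list <- list(res_a$windows, res_b$windows)
  names(windows_list) <- c(sp_a, sp_b)
  gene_he_list <- list(res_a$gene_he, res_b$gene_he)
  names(gene_he_list) <- c(sp_a, sp_b)
  orth_list <- list(orth)
  names(orth_list) <- paste0(sp_a, "|", sp_b)
  he_matrix <- population_he_matrix(windows_list, gene_he_list, orth_list)
  write_results_tsv(he_matrix, file.path(out_dir, "he_matrix.tsv"), list())

  manifest <- list(
    poolscan_version = as.character(packageVersion("poolscan")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    species = c(a = sp_a, b = sp_b),
    config = cfg,
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    candidates_a = res_a$candidates, candidates_b = res_b$candidates,
    nullw_ab = nullw_ab, nullw_ba = nullw_ba,
    correlations = correlations, extreme_overlap = overlap,
    he_matrix = he_matrix, orthologs = orth,
    species_a = res_a, species_b = res_b,
    manifest = manifest
  ))
}
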