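#' Default pipeline configuration
#'
#' Threshold defaults are the study's printed values: edit calling at
#' FDR < 0.05 with differential editing frequency > 0.1 and a minimum depth
#' of 10 reads per condition; mRNA filters FDR < 0.05 / FC >= 2; protein
#' filters FDR < 0.1 / FC >= 2; pair asymmetry |log2FC| >= 0.6 (NUMB ratio
#' rule 2-fold); polarity |log2FC| > 0.6.
#'
#' @return nested configuration list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    simulate = list(
      edits = list(n_genes = 200, sites_per_gene = 1.5,
                   n_replicates_per_condition = 3,
                   coverage_mean = 100, coverage_dispersion = 5,
                   baseline_edit_rate = 0.005, true_site_fraction = 0.3,
                   effect_delta = 0.3, overdispersion_rho = 0.02,
                   motif = "ACUUAG", motif_offset_sd = 50),
      expression = list(frac_targets_down_rna = 12 / 534,
                        frac_targets_down_protein = 63 / 534,
                        n_rna_down = 40, n_protein_down = 50,
                        noise_sd = 0.25, n_replicates = 3),
      pairs = list(n_pairs = 300,
                   mix = c(sym_renewal = 0.4, sym_commitment = 0.3,
                           asymmetric = 0.3),
                   noise_cv = 0.05, coseg_prob = 0.8),
      polarity = list(n_cells = 300, frac_polar = 0.5,
                      polar_log2fc_mean = 1.0)),
    thresholds = list(alpha = 0.05, min_delta = 0.1, min_depth = 10,
                      method = "fisher_pooled",
                      rna_fdr = 0.05, rna_fc = 2, prot_fdr = 0.1, prot_fc = 2,
                      pair_log2fc = 0.6, polarity_log2fc = 0.6, numb_ratio = 2),
    motif = list(window = 250, kmin = 4, kmax = 7),
    io = list(out_dir = "tribetools_run")),
    class = "pipeline_config")
}

merge_config <- function(defaults, override, path = character()) {
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(c(paste(path, collapse = "."), bad), collapse = ".")),
         call. = FALSE)
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]], c(path, nm))
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

config_overrides <- function(defaults, cfg, path = character()) {
  out <- character(0)
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      out <- c(out, config_overrides(defaults[[nm]], cfg[[nm]], c(path, nm)))
    } else if (!isTRUE(all.equal(unname(unlist(defaults[[nm]])),
                                 unname(unlist(cfg[[nm]]))))) {
      out <- c(out, paste(c(path, nm), collapse = "."))
    }
  }
  out
}

#' Load a pipeline configuration from YAML (or JSON)
#'
#' Unknown keys are rejected; missing keys take their defaults (the study's
#' printed thresholds).  An empty or absent file yields the full default
#' configuration.  Keys whose values differ from the defaults are recorded
#' in `attr(cfg, "overrides")` and echoed into the run report.
#'
#' @param path YAML/JSON file path, or `NULL` for pure defaults.
#' @return `pipeline_config` list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  override <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                                 call. = FALSE)
    override <- yaml::read_yaml(path)
  }
  cfg <- if (is.null(override)) defaults else merge_config(defaults, override)
  # re-validate the numeric thresholds
  th <- cfg$thresholds
  for (f in c("alpha", "min_delta", "rna_fdr", "prot_fdr"))
    if (!is.numeric(th[[f]]) || th[[f]] <= 0 || th[[f]] > 1)
      stop_config(paste0("thresholds.", f), "must be in (0,1]")
  if (is.list(cfg$simulate$pairs$mix)) cfg$simulate$pairs$mix <-
      unlist(cfg$simulate$pairs$mix)
  attr(cfg, "overrides") <- config_overrides(defaults, cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic-to-report pipeline
#'
#' Orchestrates simulate -> call-edits -> motif -> integrate ->
#' score-division on synthetic data generated from the configuration, writes
#' all stage outputs under `config$io$out_dir`, and returns a run report
#' whose record counts are cross-checked against the written files.
#'
#' @param config a `pipeline_config` (see [load_config()]).
#' @param out_dir overrides `config$io$out_dir` when given.
#' @return list of class `run_report`: per-stage record counts, filter
#'   survival counts, seed, elapsed seconds per stage, configuration echo
#'   with overridden keys, and output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- config
  if (is.null(out_dir)) out_dir <- cfg$io$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  report <- list(seed = seed, stages = list(),
                 config_overrides = attr(cfg, "overrides"),
                 paths = character(0))
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    report$stages[[name]]$elapsed_s <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  ## stage 1: simulate
  sim <- timed("simulate", {
    ec <- do.call(edit_sim_config, c(cfg$simulate$edits, list(seed = seed)))
    simulate_edit_dataset(ec)
  })
  p_counts <- file.path(out_dir, "counts.tsv")
  write_counts_tsv(sim$counts, p_counts)
  write_transcripts_bed(sim$transcripts, file.path(out_dir, "transcripts.bed.tsv"))
  write_fasta(sim$sequences, file.path(out_dir, "sequences.fasta"))
  write_tsv(sim$truth, file.path(out_dir, "truth_sites.tsv"))
  report$stages$simulate$n_sites <- nrow(sim$counts)
  report$stages$simulate$n_true_sites <- sum(sim$truth$is_true_target)

  ## stage 2: edit calling
  th <- cfg$thresholds
  calls <- timed("call_edits",
                 call_edits(sim$counts, alpha = th$alpha, min_delta = th$min_delta,
                            min_depth = th$min_depth, method = th$method,
                            transcripts = sim$transcripts))
  p_calls <- file.path(out_dir, "edit_calls.tsv")
  write_tsv(as.data.frame(calls), p_calls)
  write_calls_vcf(calls, file.path(out_dir, "edit_calls.vcf"))
  gene_summary <- summarize_targets(calls)
  write_tsv(gene_summary$genes, file.path(out_dir, "gene_targets.tsv"))
  report$stages$call_edits$n_tested <- attr(calls, "n_tested")
  report$stages$call_edits$n_called <- nrow(calls)
  report$stages$call_edits$n_target_genes <- nrow(gene_summary$genes)

  ## stage 3: motif analysis
  mres <- timed("motif", {
    fg_w <- extract_context_sequences(calls, sim$transcripts, sim$sequences,
                                      window = cfg$motif$window)
    target_genes <- unique(calls$gene)
    bg_pool <- setdiff(unique(sim$counts$gene), target_genes)
    bg_w <- background_windows(bg_pool, sim$transcripts, sim$sequences,
                               n = max(20, nrow(fg_w)),
                               window = cfg$motif$window,
                               seed = child_seed(seed, 5L))
    ranking <- if (nrow(fg_w) >= 10 && nrow(bg_w) >= 10)
      rank_kmers(fg_w$seq, bg_w$seq, k_range = c(cfg$motif$kmin, cfg$motif$kmax))
    else NULL
    top_motif <- if (!is.null(ranking)) ranking$kmer[1] else cfg$simulate$edits$motif
    dist <- nearest_motif_distances(fg_w, top_motif, window = cfg$motif$window)
    list(fg = fg_w, ranking = ranking, distances = dist, top_motif = top_motif)
  })
  if (!is.null(mres$ranking))
    write_tsv(as.data.frame(mres$ranking), file.path(out_dir, "motif_ranking.tsv"))
  dprof <- mres$distances[[1]]$all
  write_tsv(data.frame(distance = dprof$distances),
            file.path(out_dir, "motif_distances.tsv"))
  if (!is.null(dprof$density))
    write_tsv(dprof$density, file.path(out_dir, "motif_density_grid.tsv"))
  report$stages$motif$n_windows <- nrow(mres$fg)
  report$stages$motif$top_motif <- mres$top_motif
  report$stages$motif$n_distances <- length(dprof$distances)

  ## stage 4: multi-omics integration
  integ <- timed("integrate", {
    genes <- unique(sim$counts$gene)
    target_genes <- unique(calls$gene)
    ex <- do.call(simulate_expression_tables,
                  c(list(genes = genes, target_genes = target_genes,
                         seed = seed), cfg$simulate$expression))
    norm <- normalize_protein_matrix(ex$protein_matrix)
    prot_tested <- protein_log2fc_test(norm)
    rna_down <- filter_de(ex$rna, th$rna_fdr, th$rna_fc, "down")
    prot_down <- filter_de(ex$protein, th$prot_fdr, th$prot_fc, "down")
    vc <- venn_counts(list(targets = target_genes, rna_down = rna_down,
                           protein_down = prot_down))
    gene_counts <- gene_summary$genes[c("gene", "n_edit_sites")]
    corr <- if (nrow(merge(gene_counts, ex$rna, by = "gene")) >= 10)
      edits_vs_expression_correlation(gene_counts, ex$rna) else NULL
    list(expr = ex, prot_tested = prot_tested, venn = vc, corr = corr)
  })
  write_tsv(integ$expr$rna, file.path(out_dir, "rna_expression.tsv"))
  write_tsv(integ$expr$protein, file.path(out_dir, "protein_expression.tsv"))
  venn_df <- data.frame(region = names(integ$venn$counts),
                        count = as.integer(integ$venn$counts))
  write_tsv(venn_df, file.path(out_dir, "venn_regions.tsv"))
  jsonlite::write_json(integ$venn$genes, file.path(out_dir, "venn_regions.json"),
                       auto_unbox = FALSE)
  report$stages$integrate$venn <- stats::setNames(as.integer(integ$venn$counts),
                                                  names(integ$venn$counts))
  report$stages$integrate$spearman_rho <-
    if (!is.null(integ$corr)) integ$corr$rho else NA

  ## stage 5: division scoring
  div <- timed("score_division", {
    prs <- do.call(simulate_daughter_pairs,
                   c(list(seed = seed), cfg$simulate$pairs))
    cls <- classify_pairs(prs, rule = "numb", high_threshold = "auto")
    summ <- summarize_divisions(cls)
    cells <- do.call(simulate_polarity_cells,
                     c(list(seed = seed), cfg$simulate$polarity))
    cells$polarity <- score_polarity(cells$h1, cells$h2, th$polarity_log2fc)
    list(pairs = cls, summary = summ, cells = cells)
  })
  write_tsv(div$pairs, file.path(out_dir, "daughter_pairs_classified.tsv"))
  write_tsv(div$summary$fractions, file.path(out_dir, "division_summary.tsv"))
  write_tsv(div$cells, file.path(out_dir, "polarity_cells.tsv"))
  report$stages$score_division$n_pairs <- nrow(div$pairs)
  report$stages$score_division$frac_polar <- mean(div$cells$polarity == "polar")

  ## consistency: survival counts vs written files
  stopifnot(nrow(read_tsv(p_counts)) == report$stages$simulate$n_sites,
            nrow(read_tsv(p_calls)) == report$stages$call_edits$n_called)

  report$paths <- list.files(out_dir, full.names = TRUE)
  jsonlite::write_json(
    list(seed = seed, stages = report$stages,
         config_overrides = report$config_overrides),
    file.path(out_dir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_echo.yaml"))
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d)\n", x$seed))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                paste(names(st), vapply(st, function(v)
                  paste(format(v, digits = 4), collapse = ","), character(1)),
                  sep = "=", collapse = "  ")))
  }
  if (length(x$config_overrides))
    cat("  non-default config keys:", paste(x$config_overrides, collapse = ", "), "\n")
  invisible(x)
}

#' Background windows from non-target transcripts
#'
#' Random positions on non-target transcripts, cut with the same window
#' logic as the foreground, for motif-enrichment background construction.
#'
#' @param genes character vector of background gene names.
#' @param transcripts,sequences as in [extract_context_sequences()].
#' @param n number of windows to draw.
#' @param window half-window size.
#' @param seed integer seed.
#' @return data frame as from [extract_context_sequences()].
#' @export
background_windows <- function(genes, transcripts, sequences, n, window = 250,
                               seed = 1) {
  set.seed(seed)
  if (!length(genes)) stop("no background genes available", call. = FALSE)
  gn <- sample(genes, n, replace = TRUE)
  tx <- transcripts[transcripts$gene %in% genes, ]
  ext <- tapply(seq_len(nrow(tx)), tx$chrom,
                function(i) c(min(tx$start[i]), max(tx$end[i])))
  pos <- vapply(gn, function(g) {
    b <- ext[[g]]
    b[1] + floor(stats::runif(1) * (b[2] - b[1]))
  }, numeric(1))
  fake <- data.frame(site_id = sprintf("bg%06d", seq_len(n)), gene = gn,
                     chrom = gn, pos = as.integer(pos), strand = "+",
                     stringsAsFactors = FALSE)
  extract_context_sequences(fake, transcripts, sequences, window = window)
}
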