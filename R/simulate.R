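#' Configuration for the synthetic editing experiment
#'
#' Describes the generative model for a HyperTRIBE-style experiment: an
#' RBP-ADAR fusion condition (`S_ADAR`) versus an empty-vector control
#' (`EV`).  Alternate-read counts at each candidate site are beta-binomial;
#' truly bound sites gain `effect_delta` editing frequency in the fusion
#' condition only, and their transcripts carry a planted binding motif near
#' the edit site.
#'
#' Defaults mirror the emulated study design: 3 replicates per condition,
#' a low empty-vector background editing rate (0.005), the `ACUUAG` motif,
#' and single-isoform plus-strand transcripts of 200 nt 5'UTR, 900 nt CDS,
#' 600 nt 3'UTR.  Candidate sites fall mostly in the 3'UTR
#' (`region_weights`), matching the observed genic-location skew of edits.
#'
#' @param n_genes number of genes (one transcript each).
#' @param sites_per_gene mean candidate sites per gene (>= 1); sites per
#'   gene are `1 + Poisson(sites_per_gene - 1)`.
#' @param n_replicates_per_condition replicates in each of S_ADAR and EV.
#' @param coverage_mean,coverage_dispersion negative-binomial read depth per
#'   site and sample (mean, size); floored at 1 read.
#' @param baseline_edit_rate background editing frequency in `[0,1)`.
#' @param true_site_fraction fraction of sites that are truly RBP-bound.
#' @param effect_delta editing-frequency increase at true sites in S_ADAR;
#'   `effect_delta = 0` means no true targets at all (null configuration).
#' @param overdispersion_rho beta-binomial intra-class correlation in `[0,1)`.
#' @param motif planted k-mer, RNA alphabet (`A`, `C`, `G`, `U`).
#' @param motif_offset_sd standard deviation (bases) of the planted motif's
#'   offset from its edit site; offsets are clamped to +/-200 so every true
#'   site has its motif well within a 250-base search window.
#' @param utr5_len,cds_len,utr3_len transcript architecture in nt.
#' @param region_weights sampling weights for candidate-site location, named
#'   `5UTR`, `CDS`, `3UTR`.
#' @param seed master seed; all randomness derives from it.
#' @return validated list of class `edit_sim_config`.
#' @export
edit_sim_config <- function(n_genes = 200,
                            sites_per_gene = 1.5,
                            n_replicates_per_condition = 3,
                            coverage_mean = 100,
                            coverage_dispersion = 5,
                            baseline_edit_rate = 0.005,
                            true_site_fraction = 0.3,
                            effect_delta = 0.3,
                            overdispersion_rho = 0.02,
                            motif = "ACUUAG",
                            motif_offset_sd = 50,
                            utr5_len = 200, cds_len = 900, utr3_len = 600,
                            region_weights = c(`5UTR` = 0.1, CDS = 0.3, `3UTR` = 0.6),
                            seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              sites_per_gene = sites_per_gene,
              n_replicates_per_condition = as.integer(n_replicates_per_condition),
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              baseline_edit_rate = baseline_edit_rate,
              true_site_fraction = true_site_fraction,
              effect_delta = effect_delta,
              overdispersion_rho = overdispersion_rho,
              motif = toupper(motif),
              motif_offset_sd = motif_offset_sd,
              utr5_len = as.integer(utr5_len), cds_len = as.integer(cds_len),
              utr3_len = as.integer(utr3_len),
              region_weights = region_weights,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop_config("n_genes", "must be >= 1")
  if (cfg$sites_per_gene < 1) stop_config("sites_per_gene", "must be >= 1")
  if (cfg$n_replicates_per_condition < 1L)
    stop_config("n_replicates_per_condition", "must be >= 1")
  if (cfg$coverage_mean <= 0) stop_config("coverage_mean", "must be > 0")
  if (cfg$coverage_dispersion <= 0) stop_config("coverage_dispersion", "must be > 0")
  check_fraction(cfg$baseline_edit_rate, "baseline_edit_rate", closed_top = FALSE)
  check_fraction(cfg$true_site_fraction, "true_site_fraction")
  check_fraction(cfg$effect_delta, "effect_delta")
  check_fraction(cfg$overdispersion_rho, "overdispersion_rho", closed_top = FALSE)
  if (cfg$baseline_edit_rate + cfg$effect_delta > 1)
    stop_config("effect_delta", "baseline_edit_rate + effect_delta must be <= 1")
  if (!grepl("^[ACGU]+$", cfg$motif)) stop_config("motif", "must be over {A,C,G,U}")
  if (cfg$motif_offset_sd < 0) stop_config("motif_offset_sd", "must be >= 0")
  if (!all(c("5UTR", "CDS", "3UTR") %in% names(cfg$region_weights)))
    stop_config("region_weights", "must name 5UTR, CDS and 3UTR")
  structure(cfg, class = "edit_sim_config")
}

#' Simulate a HyperTRIBE-style editing dataset with known truth
#'
#' Generates per-site reference/alternate read counts for S_ADAR and EV
#' samples, single-isoform transcript models, genomic sequences with the
#' binding motif planted near every true site, and a truth table.  Each gene
#' lives on its own contig (named after the gene) so genomic and transcript
#' coordinates coincide; all transcripts are plus-strand single isoforms.
#'
#' At every site the reference base is A (the A-to-I convention: edits read
#' as A-to-G on the plus strand).  Alternate counts are
#' `BetaBinomial(depth, p, rho)` with `p = baseline_edit_rate` everywhere
#' except true sites in S_ADAR samples, where
#' `p = baseline_edit_rate + effect_delta`.
#'
#' @param config an [edit_sim_config()].
#' @return list with elements `counts` (site-by-sample count table; columns
#'   `site_id`, `gene`, `chrom`, `pos` (0-based), `strand`, then
#'   `ref_<sample>`/`alt_<sample>` pairs), `transcripts` (BED-like 0-based
#'   half-open region intervals), `sequences` (named character vector, DNA
#'   alphabet), `truth` (per-site ground truth), and `samples`
#'   (sample/condition map).
#' @export
simulate_edit_dataset <- function(config) {
  stopifnot(inherits(config, "edit_sim_config"))
  set.seed(child_seed(config$seed, 1L))
  g <- config
  tx_len <- g$utr5_len + g$cds_len + g$utr3_len
  genes <- sprintf("gene%05d", seq_len(g$n_genes))
  region_bounds <- list(
    `5UTR` = c(0L, g$utr5_len),
    CDS    = c(g$utr5_len, g$utr5_len + g$cds_len),
    `3UTR` = c(g$utr5_len + g$cds_len, tx_len))

  n_sites_per_gene <- 1L + stats::rpois(g$n_genes, g$sites_per_gene - 1)
  site_gene <- rep(genes, n_sites_per_gene)
  n_sites <- length(site_gene)
  w <- g$region_weights[c("5UTR", "CDS", "3UTR")]
  site_region <- sample(names(w), n_sites, replace = TRUE, prob = w / sum(w))
  lo <- vapply(region_bounds, `[`, integer(1), 1L)[site_region]
  hi <- vapply(region_bounds, `[`, integer(1), 2L)[site_region]
  site_pos <- lo + floor(stats::runif(n_sites) * (hi - lo))
  # distinct positions within a gene (collisions nudged deterministically)
  key <- paste(site_gene, site_pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    site_pos[dup] <- (site_pos[dup] + 1L) %% tx_len
    key <- paste(site_gene, site_pos)
  }
  is_true <- if (g$effect_delta > 0) {
    stats::runif(n_sites) < g$true_site_fraction
  } else rep(FALSE, n_sites)

  site_id <- sprintf("site%06d", seq_len(n_sites))
  nrep <- g$n_replicates_per_condition
  samples <- c(paste0("S_ADAR_", seq_len(nrep)), paste0("EV_", seq_len(nrep)))
  condition <- condition_of(samples)

  p_mat <- matrix(g$baseline_edit_rate, n_sites, length(samples))
  p_mat[is_true, condition == "S_ADAR"] <- g$baseline_edit_rate + g$effect_delta

  depth <- matrix(pmax(1L, stats::rnbinom(n_sites * length(samples),
                                          mu = g$coverage_mean,
                                          size = g$coverage_dispersion)),
                  n_sites, length(samples))
  alt <- matrix(rbetabinom(length(depth), as.vector(depth), as.vector(p_mat),
                           g$overdispersion_rho),
                n_sites, length(samples))
  ref <- depth - alt

  counts <- data.frame(site_id = site_id, gene = site_gene, chrom = site_gene,
                       pos = as.integer(site_pos), strand = "+",
                       stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    counts[[paste0("ref_", samples[j])]] <- as.integer(ref[, j])
    counts[[paste0("alt_", samples[j])]] <- as.integer(alt[, j])
  }

  transcripts <- do.call(rbind, lapply(names(region_bounds), function(r) {
    data.frame(chrom = genes, start = region_bounds[[r]][1],
               end = region_bounds[[r]][2], gene = genes,
               transcript_id = paste0(genes, ".t1"), region = r,
               strand = "+", stringsAsFactors = FALSE)
  }))
  transcripts <- transcripts[order(transcripts$gene, transcripts$start), ]
  rownames(transcripts) <- NULL

  sequences <- plant_sequences(genes, tx_len, counts, is_true, g)

  truth <- data.frame(site_id = site_id, gene = site_gene, region = site_region,
                      is_true_target = is_true,
                      true_delta = ifelse(is_true, g$effect_delta, 0),
                      stringsAsFactors = FALSE)

  list(counts = counts, transcripts = transcripts, sequences = sequences,
       truth = truth,
       samples = data.frame(sample = samples, condition = condition,
                            stringsAsFactors = FALSE))
}

# Random DNA backbones with the motif written near each true site and an A
# forced at every candidate-site position.  Planted motifs never cover a
# site position and never overlap one another, so the site-base A and every
# planted occurrence survive; offsets are clamped to +/-200 bases.
plant_sequences <- function(genes, tx_len, counts, is_true, g) {
  motif_dna <- chartr("U", "T", g$motif)
  k <- nchar(motif_dna)
  seqs <- vapply(genes, function(gn) {
    paste(sample(c("A", "C", "G", "T"), tx_len, replace = TRUE), collapse = "")
  }, character(1))
  max_off <- 200L
  site_pos_by_gene <- split(counts$pos, counts$gene)
  occupied <- list()  # per gene: planted motif start positions
  for (i in which(is_true)) {
    gn <- counts$gene[i]; pos <- counts$pos[i]
    want <- pos + as.integer(round(stats::rnorm(1, 0, g$motif_offset_sd)))
    lo <- max(0L, pos - max_off); hi <- min(tx_len - k, pos + max_off)
    want <- max(lo, min(hi, want))
    sites <- site_pos_by_gene[[gn]]
    occ <- occupied[[gn]]
    ok <- function(s) {
      !any(sites >= s & sites < s + k) &&
        (is.null(occ) || all(abs(occ - s) >= k))
    }
    start <- NA_integer_
    for (d in 0:(hi - lo)) {
      for (s in unique(c(want - d, want + d))) {
        if (s >= lo && s <= hi && ok(s)) { start <- s; break }
      }
      if (!is.na(start)) break
    }
    if (is.na(start)) start <- want  # pathological crowding; still in window
    substr(seqs[gn], start + 1L, start + k) <- motif_dna
    occupied[[gn]] <- c(occ, start)
  }
  for (i in seq_len(nrow(counts))) {
    gn <- counts$gene[i]; pos <- counts$pos[i]
    occ <- occupied[[gn]]
    if (is.null(occ) || !any(pos >= occ & pos < occ + k))
      substr(seqs[gn], pos + 1L, pos + 1L) <- "A"
  }
  seqs
}

#' Simulate matched transcriptome and proteome differential-expression tables
#'
#' Builds gene-level log2 fold-change / FDR tables for mRNA and protein
#' layers with a planted structure of direct-target regulation, plus a raw
#' protein intensity matrix (2 groups of `n_replicates` samples).  A chosen
#' fraction of the direct-target genes is planted as protein-downregulated;
#' a (smaller) fraction is planted as downregulated in both layers, drawn
#' from within the protein-down targets (co-regulated direct targets).  The
#' total down-set sizes are padded with non-target genes.
#'
#' Planted "down" genes receive `log2FC <= -1` and an FDR below the layer's
#' cutoff (mRNA 0.05, protein 0.1); all other genes receive FDR above the
#' cutoff, so threshold filters recover the planted sets exactly.
#'
#' @param genes character vector, the gene universe.
#' @param target_genes subset of `genes`: the direct-target list.
#' @param frac_targets_down_rna fraction of targets downregulated at both
#'   mRNA and protein level.
#' @param frac_targets_down_protein fraction of targets downregulated at the
#'   protein level.
#' @param n_rna_down,n_protein_down total sizes of the down-regulated sets
#'   (targets plus padding non-targets).
#' @param noise_sd standard deviation of null log2 fold changes.
#' @param n_replicates samples per group in the intensity matrix.
#' @param seed integer seed.
#' @return list: `rna` and `protein` expression tables (`gene`, `log2fc`,
#'   `fdr`, `layer`), `protein_matrix` (raw intensities, genes x samples,
#'   group labels in `attr(,"groups")`), and `truth` (planted sets).
#' @export
simulate_expression_tables <- function(genes, target_genes,
                                       frac_targets_down_rna = 12 / 534,
                                       frac_targets_down_protein = 63 / 534,
                                       n_rna_down = 561,
                                       n_protein_down = 803,
                                       noise_sd = 0.25,
                                       n_replicates = 3,
                                       seed = 1) {
  if (!length(genes)) stop("empty gene universe", call. = FALSE)
  genes <- unique(genes)
  if (!all(target_genes %in% genes))
    stop("target_genes must be a subset of the gene universe", call. = FALSE)
  check_fraction(frac_targets_down_rna, "frac_targets_down_rna")
  check_fraction(frac_targets_down_protein, "frac_targets_down_protein")
  set.seed(child_seed(seed, 2L))

  nt <- length(target_genes)
  n_prot_t <- round(frac_targets_down_protein * nt)
  n_rna_t <- round(frac_targets_down_rna * nt)
  if (n_rna_t > n_prot_t)
    stop("frac_targets_down_rna must not exceed frac_targets_down_protein ",
         "(mRNA-down targets are planted within the protein-down targets)",
         call. = FALSE)
  prot_targets <- sample(target_genes, n_prot_t)
  rna_targets <- sample(prot_targets, n_rna_t)

  nontargets <- setdiff(genes, target_genes)
  pad_rna <- max(0L, n_rna_down - n_rna_t)
  pad_prot <- max(0L, n_protein_down - n_prot_t)
  if (pad_rna + pad_prot > length(nontargets))
    stop("gene universe too small for the requested down-set sizes", call. = FALSE)
  pad <- sample(nontargets, pad_rna + pad_prot)
  rna_down <- c(rna_targets, pad[seq_len(pad_rna)])
  prot_down <- c(prot_targets, pad[pad_rna + seq_len(pad_prot)])

  mk_table <- function(down, fdr_cut, layer) {
    lfc <- stats::rnorm(length(genes), 0, noise_sd)
    fdr <- stats::runif(length(genes), fdr_cut, 1)
    idx <- match(down, genes)
    lfc[idx] <- -1 - abs(stats::rnorm(length(idx), 0.5, 0.4))
    fdr[idx] <- stats::runif(length(idx), 0, fdr_cut * 0.8)
    data.frame(gene = genes, log2fc = lfc, fdr = fdr, layer = layer,
               stringsAsFactors = FALSE)
  }
  rna <- mk_table(rna_down, 0.05, "mRNA")
  protein <- mk_table(prot_down, 0.1, "protein")

  # raw intensity matrix consistent with the planted protein fold changes
  base <- 2^stats::rnorm(length(genes), 20, 2)
  wt <- matrix(base, length(genes), n_replicates) *
    2^matrix(stats::rnorm(length(genes) * n_replicates, 0, noise_sd / 2),
             length(genes), n_replicates)
  ko <- matrix(base * 2^protein$log2fc, length(genes), n_replicates) *
    2^matrix(stats::rnorm(length(genes) * n_replicates, 0, noise_sd / 2),
             length(genes), n_replicates)
  m <- cbind(ko, wt)
  dimnames(m) <- list(genes, c(paste0("KO_", seq_len(n_replicates)),
                               paste0("WT_", seq_len(n_replicates))))
  attr(m, "groups") <- rep(c("KO", "WT"), each = n_replicates)

  list(rna = rna, protein = protein, protein_matrix = m,
       truth = list(targets = target_genes, rna_down = rna_down,
                    protein_down = prot_down,
                    targets_protein_down = prot_targets,
                    targets_both_down = rna_targets))
}

#' Simulate paired daughter-cell intensity data
#'
#' Emulates the paired daughter assay: each division is symmetric renewal
#' (both daughters low marker), symmetric commitment (both high), or
#' asymmetric (one low, one high).  Asymmetric pairs are drawn with a
#' between-daughter intensity ratio of at least 4 (well past the 2-fold
#' scoring boundary); symmetric pairs with ratio below 1.5.  Multiplicative
#' log-normal noise with coefficient of variation `noise_cv` is applied to
#' every intensity.
#'
#' With `coseg_prob` set, a second marker is generated on the same pairs:
#' it shares the pair's division class, and for asymmetric pairs the same
#' daughter is high for both markers with probability `coseg_prob`.
#'
#' @param n_pairs number of daughter pairs.
#' @param mix length-3 fractions over (sym_renewal, sym_commitment,
#'   asymmetric); must sum to 1 (tolerance 1e-9).
#' @param intensity_scales named vector `c(low=, high=)` of mean intensities.
#' @param noise_cv multiplicative noise CV (0 = noiseless).
#' @param coseg_prob optional co-segregation probability for a second marker.
#' @param genotype,replicate metadata labels (recycled).
#' @param marker marker name recorded in the table.
#' @param seed integer seed.
#' @return data frame with `pair_id`, `genotype`, `replicate`, `marker`,
#'   `i1`, `i2`, `true_class` (and `j1`, `j2` when `coseg_prob` is set).
#' @export
simulate_daughter_pairs <- function(n_pairs,
                                    mix = c(sym_renewal = 1 / 3,
                                            sym_commitment = 1 / 3,
                                            asymmetric = 1 / 3),
                                    intensity_scales = c(low = 50, high = 200),
                                    noise_cv = 0.05,
                                    coseg_prob = NULL,
                                    genotype = "WT", replicate = 1L,
                                    marker = "NUMB",
                                    seed = 1) {
  if (abs(sum(mix) - 1) > 1e-9)
    stop("mix fractions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  set.seed(child_seed(seed, 3L))
  classes <- c("sym_renewal", "sym_commitment", "asymmetric")
  cls <- sample(classes, n_pairs, replace = TRUE, prob = mix)
  low <- intensity_scales[["low"]]; high <- intensity_scales[["high"]]

  draw_marker <- function(cls, high_side) {
    base <- ifelse(cls == "sym_commitment", high, low)
    # symmetric: ratio uniform in [1, 1.4]; asymmetric: ratio >= 4
    sym_ratio <- stats::runif(length(cls), 1, 1.4)
    asym_ratio <- 4 * 2^abs(stats::rnorm(length(cls), 0, 0.3))
    i_lo <- base
    i1 <- ifelse(cls == "asymmetric",
                 ifelse(high_side == 1, i_lo * asym_ratio, i_lo),
                 ifelse(high_side == 1, base * sqrt(sym_ratio), base / sqrt(sym_ratio)))
    i2 <- ifelse(cls == "asymmetric",
                 ifelse(high_side == 1, i_lo, i_lo * asym_ratio),
                 ifelse(high_side == 1, base / sqrt(sym_ratio), base * sqrt(sym_ratio)))
    if (noise_cv > 0) {
      sdl <- sqrt(log(1 + noise_cv^2))
      i1 <- i1 * stats::rlnorm(length(cls), -sdl^2 / 2, sdl)
      i2 <- i2 * stats::rlnorm(length(cls), -sdl^2 / 2, sdl)
    }
    cbind(i1, i2)
  }

  side1 <- sample(1:2, n_pairs, replace = TRUE)
  m1 <- draw_marker(cls, side1)
  out <- data.frame(pair_id = sprintf("pair%06d", seq_len(n_pairs)),
                    genotype = genotype, replicate = replicate,
                    marker = marker, i1 = m1[, 1], i2 = m1[, 2],
                    true_class = cls, stringsAsFactors = FALSE)
  if (!is.null(coseg_prob)) {
    check_fraction(coseg_prob, "coseg_prob")
    flip <- stats::runif(n_pairs) >= coseg_prob
    side2 <- ifelse(flip, 3L - side1, side1)
    m2 <- draw_marker(cls, side2)
    out$j1 <- m2[, 1]; out$j2 <- m2[, 2]
    out$true_coseg <- ifelse(cls == "asymmetric", !flip, NA)
  }
  out
}

#' Simulate single-cell polarity intensity data
#'
#' Each cell carries summed marker intensity for its two halves.  Polar
#' cells draw an absolute half-to-half log2 ratio above the 0.6 scoring
#' boundary (mean `polar_log2fc_mean`), unpolarized cells below it.
#'
#' @param n_cells number of cells.
#' @param frac_polar fraction of truly polar cells.
#' @param polar_log2fc_mean mean |log2 ratio| of polar cells (> 0.6).
#' @param noise_sd sd of the polar log2 ratio (truncated above 0.62).
#' @param genotype,replicate metadata labels.
#' @param seed integer seed.
#' @return data frame `cell_id`, `genotype`, `replicate`, `h1`, `h2`,
#'   `true_polar`.
#' @export
simulate_polarity_cells <- function(n_cells, frac_polar = 0.5,
                                    polar_log2fc_mean = 1.0,
                                    noise_sd = 0.15,
                                    genotype = "WT", replicate = 1L,
                                    seed = 1) {
  check_fraction(frac_polar, "frac_polar")
  set.seed(child_seed(seed, 4L))
  polar <- stats::runif(n_cells) < frac_polar
  lfc <- ifelse(polar,
                pmax(0.62, stats::rnorm(n_cells, polar_log2fc_mean, noise_sd)),
                stats::runif(n_cells, 0, 0.55))
  sgn <- sample(c(-1, 1), n_cells, replace = TRUE)
  base <- 100
  data.frame(cell_id = sprintf("cell%06d", seq_len(n_cells)),
             genotype = genotype, replicate = replicate,
             h1 = base * 2^(sgn * lfc / 2), h2 = base * 2^(-sgn * lfc / 2),
             true_polar = polar, stringsAsFactors = FALSE)
}
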