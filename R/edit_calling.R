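#' Per-sample editing frequencies and per-condition means
#'
#' The editing frequency of a site in one sample is `alt / (ref + alt)`.
#' Samples with zero depth at a site do not contribute to that site's
#' condition mean; sites with zero depth across an entire condition are
#' flagged (`testable = FALSE`) and excluded from calling.  Condition means
#' are unweighted across contributing samples.
#'
#' @param counts site count table as produced by [simulate_edit_dataset()]
#'   or read with [read_counts_tsv()]: columns `site_id`, `gene`, `chrom`,
#'   `pos`, `strand`, then `ref_<sample>`/`alt_<sample>` pairs where the
#'   sample name starts with its condition (`S_ADAR` or `EV`).
#' @return data frame: `site_id`, `f_adar`, `f_ev`, `delta_f`
#'   (`f_adar - f_ev`), per-condition contributing-sample counts, and
#'   `testable`.
#' @export
compute_site_frequencies <- function(counts) {
  parsed <- parse_count_columns(counts)
  ref <- parsed$ref; alt <- parsed$alt; cond <- parsed$condition
  if (any(ref < 0) || any(alt < 0))
    stop("negative read counts in count table", call. = FALSE)
  depth <- ref + alt
  freq <- alt / depth          # NaN where depth == 0
  freq[depth == 0] <- NA_real_
  cond_mean <- function(cc) rowMeans(freq[, cond == cc, drop = FALSE], na.rm = TRUE)
  n_contrib <- function(cc) rowSums(depth[, cond == cc, drop = FALSE] > 0)
  f_adar <- cond_mean("S_ADAR"); f_ev <- cond_mean("EV")
  n_adar <- n_contrib("S_ADAR"); n_ev <- n_contrib("EV")
  f_adar[n_adar == 0] <- NA_real_; f_ev[n_ev == 0] <- NA_real_
  data.frame(site_id = counts$site_id,
             f_adar = f_adar, f_ev = f_ev, delta_f = f_adar - f_ev,
             n_samples_adar = n_adar, n_samples_ev = n_ev,
             testable = n_adar > 0 & n_ev > 0,
             stringsAsFactors = FALSE)
}

parse_count_columns <- function(counts) {
  ref_cols <- grep("^ref_", names(counts), value = TRUE)
  alt_cols <- grep("^alt_", names(counts), value = TRUE)
  samples <- sub("^ref_", "", ref_cols)
  if (!length(samples) || !setequal(samples, sub("^alt_", "", alt_cols)))
    stop("count table must have matching ref_/alt_ columns", call. = FALSE)
  alt_cols <- paste0("alt_", samples)
  cond <- condition_of(samples)
  if (!all(cond %in% c("S_ADAR", "EV")))
    stop("sample conditions must be S_ADAR or EV (encoded in column names)",
         call. = FALSE)
  if (length(unique(cond)) < 2L)
    stop("need at least one sample per condition", call. = FALSE)
  list(ref = as.matrix(counts[ref_cols]), alt = as.matrix(counts[alt_cols]),
       samples = samples, condition = cond)
}

# Two-sided conditional exact (Fisher) p for a 2x2 table given as pooled
# (alt, ref) per condition.  Probabilities from the hypergeometric mass;
# two-sided p sums all tables with mass <= observed * (1 + 1e-7), the
# standard convention.  Vectorized over sites.
fisher_pooled_p <- function(alt_a, ref_a, alt_e, ref_e) {
  vapply(seq_along(alt_a), function(i) {
    m <- alt_a[i] + alt_e[i]              # total alt
    nn <- ref_a[i] + ref_e[i]             # total ref
    k <- alt_a[i] + ref_a[i]              # S_ADAR depth
    if (m + nn == 0) return(NA_real_)
    support <- max(0, k - nn):min(k, m)
    d <- stats::dhyper(support, m, nn, k)
    sum(d[d <= d[support == alt_a[i]] * (1 + 1e-7)])
  }, numeric(1))
}

# beta-binomial negative log-likelihood for one site; x, n per sample
bb_negll <- function(x, n, p, rho) {
  p <- min(max(p, 1e-9), 1 - 1e-9)
  rho <- min(max(rho, 1e-9), 1 - 1e-6)
  -sum(dbetabinom(x, n, p, rho, log = TRUE))
}

# Likelihood-ratio test: shared mean vs per-condition means, shared
# overdispersion; p from chi-square, df = 1.
betabinom_lrt_p <- function(alt, ref, cond) {
  n <- alt + ref
  use <- n > 0
  x <- alt[use]; n <- n[use]; cc <- cond[use]
  if (length(unique(cc)) < 2L) return(NA_real_)
  p0 <- sum(x) / sum(n)
  xa <- x[cc == "S_ADAR"]; na <- n[cc == "S_ADAR"]
  xe <- x[cc == "EV"]; ne <- n[cc == "EV"]
  p1a <- sum(xa) / sum(na); p1e <- sum(xe) / sum(ne)
  null_fit <- stats::optim(c(stats::qlogis(min(max(p0, 1e-4), 1 - 1e-4)), -3),
    function(th) bb_negll(x, n, stats::plogis(th[1]), stats::plogis(th[2])),
    method = "Nelder-Mead")
  alt_fit <- stats::optim(
    c(stats::qlogis(min(max(p1a, 1e-4), 1 - 1e-4)),
      stats::qlogis(min(max(p1e, 1e-4), 1 - 1e-4)), -3),
    function(th) {
      bb_negll(xa, na, stats::plogis(th[1]), stats::plogis(th[3])) +
        bb_negll(xe, ne, stats::plogis(th[2]), stats::plogis(th[3]))
    },
    method = "Nelder-Mead")
  lr <- max(0, 2 * (null_fit$value - alt_fit$value))
  stats::pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Differential-editing p-value for one site
#'
#' Two statistical layers are offered.  `fisher_pooled` (default) pools
#' replicate reads within each condition and applies the two-sided Fisher
#' exact test to the 2x2 table of summed (alt, ref) counts.
#' `betabinom_lrt` is a replicate-aware likelihood-ratio test of a shared
#' editing mean against per-condition means under a beta-binomial with
#' shared overdispersion (chi-square reference, df 1).
#'
#' @param alt,ref per-sample alternate and reference counts.
#' @param condition per-sample condition labels (`S_ADAR` / `EV`).
#' @param method `"fisher_pooled"` or `"betabinom_lrt"`.
#' @return p-value (NA when either condition has no covered sample).
#' @export
test_site <- function(alt, ref, condition, method = c("fisher_pooled", "betabinom_lrt")) {
  method <- match.arg(method)
  stopifnot(length(alt) == length(ref), length(alt) == length(condition))
  if (any(alt < 0) || any(ref < 0)) stop("negative counts", call. = FALSE)
  depth <- alt + ref
  covered <- tapply(depth > 0, condition, any)
  if (!all(c("S_ADAR", "EV") %in% names(covered)) || !all(covered)) {
    warning("site skipped: a condition has no covered sample")
    return(NA_real_)
  }
  if (method == "fisher_pooled") {
    a <- condition == "S_ADAR"
    fisher_pooled_p(sum(alt[a]), sum(ref[a]), sum(alt[!a]), sum(ref[!a]))
  } else {
    betabinom_lrt_p(alt, ref, condition)
  }
}

#' Call significant differential-editing events
#'
#' Applies the calling standard: Benjamini-Hochberg FDR `q < alpha`
#' (default 0.05) and differential editing frequency
#' `delta_f = f_adar - f_ev > min_delta` (default 0.1, strict).  Sites must
#' carry at least `min_depth` summed reads in each condition to be tested;
#' BH is applied once across all tested sites of the dataset.  Output is
#' sorted by `q`, then decreasing `delta_f`, then `site_id`.
#'
#' @param counts site count table (see [compute_site_frequencies()]).
#' @param alpha FDR threshold (strict `<`).
#' @param min_delta differential-frequency threshold (strict `>`).
#' @param min_depth minimum summed reads per condition for a site to enter
#'   testing.
#' @param method per-site test, see [test_site()].
#' @param transcripts optional transcript models; when given, calls are
#'   annotated with genic region via [annotate_sites()].
#' @return data frame of class `edit_calls`: one row per called site with
#'   `site_id`, `gene`, `chrom`, `pos`, `strand`, `f_adar`, `f_ev`,
#'   `delta_f`, `p_value`, `q_value` (and `region` when annotated).
#'   Attributes: `n_sites`, `n_tested`, `tested` (full tested table),
#'   `thresholds`, `method`.
#' @export
call_edits <- function(counts, alpha = 0.05, min_delta = 0.1, min_depth = 10,
                       method = c("fisher_pooled", "betabinom_lrt"),
                       transcripts = NULL) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0,1]", call. = FALSE)
  if (!is.numeric(min_delta) || min_delta <= 0 || min_delta > 1)
    stop("min_delta must be in (0,1]", call. = FALSE)
  empty <- counts[0, c("site_id", "gene", "chrom", "pos", "strand")]
  empty$f_adar <- empty$f_ev <- empty$delta_f <-
    empty$p_value <- empty$q_value <- numeric(0)
  if (!nrow(counts))
    return(structure(empty, class = c("edit_calls", "data.frame"),
                     n_sites = 0L, n_tested = 0L, tested = empty,
                     thresholds = c(alpha = alpha, min_delta = min_delta,
                                    min_depth = min_depth),
                     method = method))

  parsed <- parse_count_columns(counts)
  freqs <- compute_site_frequencies(counts)
  cond <- parsed$condition
  depth <- parsed$ref + parsed$alt
  dep_a <- rowSums(depth[, cond == "S_ADAR", drop = FALSE])
  dep_e <- rowSums(depth[, cond == "EV", drop = FALSE])
  tested_idx <- which(freqs$testable & dep_a >= min_depth & dep_e >= min_depth)

  a <- cond == "S_ADAR"
  if (method == "fisher_pooled") {
    p <- fisher_pooled_p(rowSums(parsed$alt[tested_idx, a, drop = FALSE]),
                         rowSums(parsed$ref[tested_idx, a, drop = FALSE]),
                         rowSums(parsed$alt[tested_idx, !a, drop = FALSE]),
                         rowSums(parsed$ref[tested_idx, !a, drop = FALSE]))
  } else {
    p <- vapply(tested_idx, function(i)
      betabinom_lrt_p(parsed$alt[i, ], parsed$ref[i, ], cond), numeric(1))
  }
  q <- stats::p.adjust(p, method = "BH")

  tested <- data.frame(counts[tested_idx, c("site_id", "gene", "chrom", "pos", "strand")],
                       f_adar = freqs$f_adar[tested_idx],
                       f_ev = freqs$f_ev[tested_idx],
                       delta_f = freqs$delta_f[tested_idx],
                       p_value = p, q_value = q,
                       stringsAsFactors = FALSE)
  called <- tested[!is.na(tested$q_value) & tested$q_value < alpha &
                     tested$delta_f > min_delta, ]
  ord <- order(called$q_value, -called$delta_f, called$site_id)
  called <- called[ord, ]
  rownames(called) <- NULL
  out <- structure(called, class = c("edit_calls", "data.frame"),
                   n_sites = nrow(counts), n_tested = nrow(tested),
                   tested = tested,
                   thresholds = c(alpha = alpha, min_delta = min_delta,
                                  min_depth = min_depth),
                   method = method)
  if (!is.null(transcripts)) out <- annotate_sites(out, transcripts)
  out
}

#' @export
print.edit_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "Differential editing calls: %d of %d tested sites (of %d total)\n",
    nrow(x), attr(x, "n_tested"), attr(x, "n_sites")))
  cat(sprintf("  standard: q < %g and delta_f > %g; min depth %g/condition; test %s\n",
              th["alpha"], th["min_delta"], th["min_depth"], attr(x, "method")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Annotate edit sites with genic region
#'
#' Assigns each call a region (`5UTR`, `CDS`, `3UTR`, `other`) by overlap
#' with transcript-model intervals.  When a site overlaps several isoform
#' intervals the fixed priority `3UTR > CDS > 5UTR` decides; sites
#' overlapping no transcript get region `other` and keep their input gene.
#'
#' @param calls `edit_calls` (or any data frame with `chrom`, `pos`, and
#'   `site_id`).
#' @param transcripts BED-like data frame: `chrom`, `start`, `end` (0-based
#'   half-open), `gene`, `transcript_id`, `region`, `strand`.
#' @return `calls` with `region` (and `gene` from the assigned transcript).
#' @export
annotate_sites <- function(calls, transcripts) {
  if (!nrow(calls)) { calls$region <- character(0); return(calls) }
  sites <- GenomicRanges::GRanges(calls$chrom,
                                  IRanges::IRanges(calls$pos + 1L, width = 1L))
  tx <- GenomicRanges::GRanges(transcripts$chrom,
                               IRanges::IRanges(transcripts$start + 1L,
                                                transcripts$end))
  hits <- GenomicRanges::findOverlaps(sites, tx)
  region <- rep("other", nrow(calls))
  gene <- if ("gene" %in% names(calls)) calls$gene else rep(NA_character_, nrow(calls))
  prio <- c(`3UTR` = 3L, CDS = 2L, `5UTR` = 1L)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    pr <- prio[transcripts$region[sh]]
    pr[is.na(pr)] <- 0L
    best <- tapply(seq_along(qh), qh, function(ii) ii[which.max(pr[ii])])
    qi <- as.integer(names(best)); si <- sh[unlist(best)]
    region[qi] <- transcripts$region[si]
    gene[qi] <- transcripts$gene[si]
  }
  calls$region <- region
  calls$gene <- gene
  calls
}

#' Collapse edit calls to gene-level targets
#'
#' One row per gene with the number of edit sites, the best (smallest)
#' q-value and the largest differential frequency, plus a sites-per-gene
#' histogram.  With a second call set, also reports the shared/unique gene
#' sets across the two datasets (e.g. two cell types).
#'
#' @param calls annotated `edit_calls`.
#' @param calls2 optional second call set.
#' @param names labels for the two call sets.
#' @return list of class `target_summary`: `genes` (gene table),
#'   `site_histogram` (table of sites-per-gene), and with `calls2` a `sets`
#'   element (`shared`, `unique1`, `unique2` gene vectors and counts).
#' @export
summarize_targets <- function(calls, calls2 = NULL, names = c("A", "B")) {
  gene_table <- function(cl) {
    if (!nrow(cl))
      return(data.frame(gene = character(0), n_edit_sites = integer(0),
                        best_q = numeric(0), max_delta_f = numeric(0)))
    sp <- split(seq_len(nrow(cl)), cl$gene)
    out <- data.frame(gene = names(sp),
                      n_edit_sites = lengths(sp),
                      best_q = vapply(sp, function(i) min(cl$q_value[i]), numeric(1)),
                      max_delta_f = vapply(sp, function(i) max(cl$delta_f[i]), numeric(1)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$best_q, -out$max_delta_f, out$gene), ]
  }
  g1 <- gene_table(calls)
  res <- list(genes = g1, site_histogram = table(g1$n_edit_sites))
  if (!is.null(calls2)) {
    g2 <- gene_table(calls2)
    shared <- intersect(g1$gene, g2$gene)
    res$sets <- list(shared = shared,
                     unique1 = setdiff(g1$gene, shared),
                     unique2 = setdiff(g2$gene, shared),
                     counts = c(stats::setNames(length(shared), "shared"),
                                stats::setNames(length(g1$gene) - length(shared),
                                                paste0(names[1], "_unique")),
                                stats::setNames(length(g2$gene) - length(shared),
                                                paste0(names[2], "_unique"))))
  }
  structure(res, class = "target_summary")
}

#' @export
print.target_summary <- function(x, ...) {
  cat(sprintf("Gene-level target summary: %d genes\n", nrow(x$genes)))
  cat("sites-per-gene histogram:\n")
  print(x$site_histogram)
  if (!is.null(x$sets)) {
    cat("cross-dataset sets:\n")
    print(x$sets$counts)
  }
  invisible(x)
}
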