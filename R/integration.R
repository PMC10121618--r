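#' Equalize total intensity across proteomics samples
#'
#' Label-free proteomics columns are rescaled so every sample's total
#' intensity equals the mean of the input totals; within-sample relative
#' proportions are unchanged.
#'
#' @param m non-negative numeric matrix, genes x samples.
#' @return rescaled matrix (same dimnames and attributes).
#' @export
normalize_protein_matrix <- function(m) {
  if (any(m < 0)) stop("protein intensities must be non-negative", call. = FALSE)
  totals <- colSums(m)
  bad <- which(totals <= 0)
  if (length(bad)) {
    nm <- if (!is.null(colnames(m))) colnames(m)[bad[1]] else as.character(bad[1])
    stop(sprintf("sample '%s' has zero total intensity", nm), call. = FALSE)
  }
  target <- mean(totals)
  out <- sweep(m, 2, target / totals, "*")
  attributes(out)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <-
    attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))]
  out
}

#' Per-gene protein log2 fold changes with one-sided rank tests
#'
#' For each gene, `log2fc = log2((mean KO + eps) / (mean WT + eps))` on
#' normalized intensities, with pseudo-count `eps` defaulting to half the
#' smallest nonzero intensity in the matrix.  Significance comes from a
#' one-sided Wilcoxon rank-sum test of the two sample groups, oriented in
#' the direction of the observed fold change (p = 1 when the fold change is
#' exactly zero); FDR by Benjamini-Hochberg across genes.  Genes with
#' all-zero intensities in both groups are dropped and counted.
#'
#' @param m normalized intensity matrix with group labels either in
#'   `attr(m, "groups")` or supplied via `groups`; exactly two groups, the
#'   first-listed level treated as the numerator (KO).
#' @param groups optional character vector of group labels per column.
#' @param pseudo_count pseudo-count; `NULL` for the default rule.
#' @return data frame `gene`, `log2fc`, `p_value`, `fdr`, `layer`
#'   (= "protein"); attribute `n_dropped`.
#' @export
protein_log2fc_test <- function(m, groups = NULL, pseudo_count = NULL) {
  if (is.null(groups)) groups <- attr(m, "groups")
  if (is.null(groups) || length(groups) != ncol(m))
    stop("need one group label per sample column", call. = FALSE)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required", call. = FALSE)
  if (min(table(groups)) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  drop <- rowSums(m) == 0
  mm <- m[!drop, , drop = FALSE]
  if (is.null(pseudo_count)) {
    nz <- mm[mm > 0]
    pseudo_count <- if (length(nz)) min(nz) / 2 else 1
  }
  ko <- mm[, groups == lv[1], drop = FALSE]
  wt <- mm[, groups == lv[2], drop = FALSE]
  lfc <- log2((rowMeans(ko) + pseudo_count) / (rowMeans(wt) + pseudo_count))
  p <- vapply(seq_len(nrow(mm)), function(i) {
    if (lfc[i] == 0) return(1)
    alt <- if (lfc[i] > 0) "greater" else "less"
    suppressWarnings(stats::wilcox.test(ko[i, ], wt[i, ],
                                        alternative = alt)$p.value)
  }, numeric(1))
  genes <- rownames(mm)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(mm)))
  out <- data.frame(gene = genes, log2fc = lfc, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    layer = "protein", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  attr(out, "pseudo_count") <- pseudo_count
  out
}

#' Threshold filter for differential-expression tables
#'
#' Fold-change boundaries are inclusive (a 2-fold filter keeps
#' `log2fc <= -1` for `down`, `log2fc >= 1` for `up`); FDR boundaries are
#' strict (`fdr < fdr_max`).
#'
#' @param table data frame with `gene`, `log2fc`, `fdr`.
#' @param fdr_max FDR cutoff (strict).
#' @param fc_min minimum fold change on the linear scale (inclusive).
#' @param direction `"down"` or `"up"`.
#' @return character vector of genes passing the filter.
#' @export
filter_de <- function(table, fdr_max, fc_min, direction = c("down", "up")) {
  if (!is.numeric(fdr_max) || fdr_max <= 0 || !is.numeric(fc_min) || fc_min <= 0)
    stop("thresholds must be positive", call. = FALSE)
  direction <- match.arg(direction)
  thr <- log2(fc_min)
  keep <- if (direction == "down") table$log2fc <= -thr else table$log2fc >= thr
  keep <- keep & table$fdr < fdr_max
  unique(table$gene[keep & !is.na(keep)])
}

#' Venn region counts for two or three gene sets
#'
#' @param sets named list of 2 or 3 character vectors (deduplicated
#'   internally).
#' @return list of class `venn_counts`: `counts` (named integer vector over
#'   exclusive regions, names like `A_only`, `A.B`, `A.B.C` built from the
#'   set names) and `genes` (the region membership lists).
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a named list", call. = FALSE)
  if (!length(sets) %in% 2:3) stop("2 or 3 sets required", call. = FALSE)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  regions <- list()
  nm <- names(sets)
  idx_sets <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(seq_along(sets), k, simplify = FALSE)), recursive = FALSE)
  for (ii in idx_sets) {
    inn <- rowSums(member[, ii, drop = FALSE]) == length(ii) &
      rowSums(member[, -ii, drop = FALSE]) == 0
    label <- if (length(ii) == 1L) paste0(nm[ii], "_only")
             else paste(nm[ii], collapse = ".")
    regions[[label]] <- universe[inn]
  }
  structure(list(counts = vapply(regions, length, integer(1)), genes = regions),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Venn region counts:\n")
  print(x$counts)
  invisible(x)
}

#' Correlation between per-gene edit-site counts and expression
#'
#' Spearman rank correlation of the number of edit sites per gene against
#' gene-level `log2fc` (or any expression measure in the `value` column
#' chosen), used to check that target selection is independent of mRNA
#' abundance.
#'
#' @param gene_counts data frame `gene`, `n_edit_sites`.
#' @param expression data frame `gene` plus the measure column.
#' @param value name of the expression column (default `log2fc`).
#' @return list: `rho`, `p_value`, `n`, `method`.  `rho` is `NA` with an
#'   explanatory `note` when a vector is constant.
#' @export
edits_vs_expression_correlation <- function(gene_counts, expression,
                                            value = "log2fc") {
  merged <- merge(gene_counts, expression, by = "gene")
  if (nrow(merged) < 10)
    stop("need at least 10 genes in common", call. = FALSE)
  x <- merged$n_edit_sites; y <- merged[[value]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = nrow(merged),
                method = "spearman", note = "constant vector: correlation undefined"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(merged),
       method = "spearman")
}
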