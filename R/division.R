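check_positive_intensity <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("intensities must be positive and finite", call. = FALSE)
}

#' Classify a NUMB daughter pair
#'
#' Ratio rule: a pair whose between-daughter intensity ratio is at least
#' 2-fold (inclusive) is asymmetric.  Pairs below 2-fold are symmetric and
#' split by mean intensity against `high_threshold`: high means symmetric
#' commitment, low means symmetric renewal.
#'
#' @param i1,i2 daughter intensities (> 0), vectorized.
#' @param high_threshold replicate-level high/low NUMB boundary; see
#'   [auto_high_threshold()] for the default derivation.
#' @return character vector over `asymmetric`, `symmetric_commitment`,
#'   `symmetric_renewal`.
#' @export
classify_numb_pair <- function(i1, i2, high_threshold) {
  check_positive_intensity(i1, i2)
  stopifnot(high_threshold > 0)
  ratio <- pmax(i1, i2) / pmin(i1, i2)
  # 1e-9 guard keeps the inclusive boundary exact under floating point
  ifelse(ratio >= 2 - 1e-9, "asymmetric",
         ifelse((i1 + i2) / 2 >= high_threshold,
                "symmetric_commitment", "symmetric_renewal"))
}

#' Classify a daughter pair on the log2 fold-change rule (LAMP1 / TMI)
#'
#' A pair is asymmetric when the absolute log2 ratio of the two daughter
#' intensities is at least `log2fc_threshold` (default 0.6, inclusive);
#' symmetric pairs are split into high/low by mean intensity against
#' `high_threshold`.
#'
#' @param i1,i2 daughter intensities (> 0), vectorized.
#' @param log2fc_threshold asymmetry boundary on |log2(i1/i2)| (inclusive).
#' @param high_threshold mean-intensity boundary for the symmetric split.
#' @return character vector over `asymmetric`, `symmetric_high`,
#'   `symmetric_low`.
#' @export
classify_log2fc_pair <- function(i1, i2, log2fc_threshold = 0.6, high_threshold) {
  check_positive_intensity(i1, i2)
  stopifnot(log2fc_threshold > 0, high_threshold > 0)
  ifelse(abs(log2(i1 / i2)) >= log2fc_threshold - 1e-9, "asymmetric",
         ifelse((i1 + i2) / 2 >= high_threshold, "symmetric_high", "symmetric_low"))
}

#' Score cell polarity from two half-cell intensity sums
#'
#' A cell is polar when the absolute log2 ratio between its two halves
#' exceeds `threshold` (default 0.6, strict: a ratio of exactly 2^0.6 is
#' unpolarized).
#'
#' @param h1,h2 half-cell summed intensities (> 0), vectorized.
#' @param threshold polarity boundary (strict `>`).
#' @return character vector over `polar`, `unpolarized`.
#' @export
score_polarity <- function(h1, h2, threshold = 0.6) {
  check_positive_intensity(h1, h2)
  # strict boundary: a ratio of exactly 2^threshold is unpolarized, with a
  # 1e-9 guard against floating-point excess
  ifelse(abs(log2(h1 / h2)) > threshold + 1e-9, "polar", "unpolarized")
}

#' Default high/low intensity threshold per replicate
#'
#' High/low expression boundaries are set per experimental replicate; the
#' default rule used here is the median of the pair mean intensities within
#' each replicate.
#'
#' @param pairs data frame with `replicate`, `i1`, `i2`.
#' @return named numeric vector, one threshold per replicate.
#' @export
auto_high_threshold <- function(pairs) {
  means <- (pairs$i1 + pairs$i2) / 2
  vapply(split(means, pairs$replicate), stats::median, numeric(1))
}

#' Classify a table of daughter pairs
#'
#' Applies [classify_numb_pair()] (rule `"numb"`) or
#' [classify_log2fc_pair()] (rule `"log2fc"`) row-wise, resolving
#' `high_threshold = "auto"` per replicate via [auto_high_threshold()].
#'
#' @param pairs data frame with `pair_id`, `genotype`, `replicate`, `i1`,
#'   `i2`.
#' @param rule `"numb"` or `"log2fc"`.
#' @param high_threshold numeric, or `"auto"` for the per-replicate median
#'   rule.
#' @param log2fc_threshold boundary for the log2fc rule.
#' @return `pairs` with a `class` column added.
#' @export
classify_pairs <- function(pairs, rule = c("numb", "log2fc"),
                           high_threshold = "auto", log2fc_threshold = 0.6) {
  rule <- match.arg(rule)
  pairs$class <- NA_character_
  for (r in unique(pairs$replicate)) {
    ii <- pairs$replicate == r
    thr <- if (identical(high_threshold, "auto")) {
      stats::median((pairs$i1[ii] + pairs$i2[ii]) / 2)
    } else high_threshold
    pairs$class[ii] <- if (rule == "numb") {
      classify_numb_pair(pairs$i1[ii], pairs$i2[ii], thr)
    } else {
      classify_log2fc_pair(pairs$i1[ii], pairs$i2[ii], log2fc_threshold, thr)
    }
  }
  pairs
}

#' Co-segregation of two markers across daughter pairs
#'
#' Builds the full contingency table of the two markers' division classes;
#' among pairs asymmetric for both markers, concordance is the fraction in
#' which the same daughter is high for both markers.  Association between
#' the two asymmetry calls is tested by Fisher's exact test on the 2x2
#' collapse (asymmetric vs not).
#'
#' @param pairs data frame with intensities `i1`, `i2` (marker 1), `j1`,
#'   `j2` (marker 2) and class columns `class1`, `class2`.
#' @return list of class `coseg_result`: `table` (contingency),
#'   `n_double_asymmetric`, `concordance` (NA when undefined),
#'   `fisher_p`.
#' @export
cosegregation_table <- function(pairs) {
  stopifnot(all(c("class1", "class2", "i1", "i2", "j1", "j2") %in% names(pairs)))
  tab <- table(marker1 = pairs$class1, marker2 = pairs$class2)
  both <- pairs$class1 == "asymmetric" & pairs$class2 == "asymmetric"
  conc <- if (!any(both)) {
    message("no doubly-asymmetric pairs: concordance undefined")
    NA_real_
  } else {
    mean((pairs$i1[both] > pairs$i2[both]) == (pairs$j1[both] > pairs$j2[both]))
  }
  a1 <- factor(pairs$class1 == "asymmetric", levels = c(FALSE, TRUE))
  a2 <- factor(pairs$class2 == "asymmetric", levels = c(FALSE, TRUE))
  fp <- if (nrow(pairs)) stats::fisher.test(table(a1, a2))$p.value else NA_real_
  structure(list(table = tab, n_double_asymmetric = sum(both),
                 concordance = conc, fisher_p = fp),
            class = "coseg_result")
}

#' @export
print.coseg_result <- function(x, ...) {
  cat("Marker co-segregation:\n")
  print(x$table)
  cat(sprintf("doubly asymmetric: %d; high-side concordance: %s; Fisher p = %.3g\n",
              x$n_double_asymmetric,
              if (is.na(x$concordance)) "undefined" else sprintf("%.3f", x$concordance),
              x$fisher_p))
  invisible(x)
}

#' Summarize division classes by genotype
#'
#' Category fractions are computed per replicate, then averaged (mean and
#' standard error) across replicates within each genotype — the replicate
#' (animal) is the experimental unit.  With exactly two genotypes and at
#' least two replicates each, a two-tailed two-sample t-test compares the
#' replicate-level fractions per category.
#'
#' @param pairs classified pair table with `genotype`, `replicate`, `class`.
#' @return list of class `division_summary`: `fractions` (genotype x
#'   category mean and sem, with n), `replicate_fractions`, and `tests`
#'   (per-category t-test results, or `NULL` with a notice when replicates
#'   are insufficient).
#' @export
summarize_divisions <- function(pairs) {
  stopifnot(all(c("genotype", "replicate", "class") %in% names(pairs)))
  cats <- sort(unique(pairs$class))
  rep_frac <- do.call(rbind, lapply(
    split(pairs, list(pairs$genotype, pairs$replicate), drop = TRUE),
    function(d) {
      tb <- table(factor(d$class, levels = cats))
      data.frame(genotype = d$genotype[1], replicate = d$replicate[1],
                 category = cats, fraction = as.numeric(tb / sum(tb)),
                 n_pairs = sum(tb), stringsAsFactors = FALSE)
    }))
  rownames(rep_frac) <- NULL
  agg <- do.call(rbind, lapply(split(rep_frac, list(rep_frac$genotype, rep_frac$category),
                                     drop = TRUE), function(d) {
    data.frame(genotype = d$genotype[1], category = d$category[1],
               mean_fraction = mean(d$fraction),
               sem = if (nrow(d) > 1) stats::sd(d$fraction) / sqrt(nrow(d)) else 0,
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  genos <- unique(rep_frac$genotype)
  n_rep <- vapply(genos, function(g)
    length(unique(rep_frac$replicate[rep_frac$genotype == g])), integer(1))
  tests <- NULL
  if (length(genos) == 2 && all(n_rep >= 2)) {
    tests <- do.call(rbind, lapply(cats, function(ct) {
      x <- rep_frac$fraction[rep_frac$genotype == genos[1] & rep_frac$category == ct]
      y <- rep_frac$fraction[rep_frac$genotype == genos[2] & rep_frac$category == ct]
      p <- if (stats::sd(c(x, y)) == 0) 1 else
        tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
      data.frame(category = ct, mean_1 = mean(x), mean_2 = mean(y),
                 p_value = p, stringsAsFactors = FALSE)
    }))
  } else if (length(genos) >= 2) {
    message("fewer than 2 replicates per genotype: tests skipped")
  }
  structure(list(fractions = agg, replicate_fractions = rep_frac, tests = tests),
            class = "division_summary")
}

#' @export
print.division_summary <- function(x, ...) {
  cat("Division-class fractions (mean +/- sem across replicates):\n")
  print(x$fractions)
  if (!is.null(x$tests)) {
    cat("two-tailed t-tests on replicate-level fractions:\n")
    print(x$tests)
  }
  invisible(x)
}
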