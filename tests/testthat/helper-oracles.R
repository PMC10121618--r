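# Independent brute-force oracles used to check the package's statistics.
# These deliberately avoid the code paths (and distribution functions) the
# implementation uses.

# Two-sided conditional exact p for a 2x2 table (alt_a, ref_a / alt_e, ref_e)
# by full enumeration of all tables with the observed margins, with each
# table's probability computed from explicit log-factorials.
oracle_fisher_p <- function(alt_a, ref_a, alt_e, ref_e) {
  lf <- function(n) lgamma(n + 1)
  m <- alt_a + alt_e; nn <- ref_a + ref_e; k <- alt_a + ref_a
  tot <- m + nn
  support <- max(0, k - nn):min(k, m)
  logp <- vapply(support, function(a) {
    b <- k - a; c <- m - a; d <- nn - b
    lf(m) + lf(nn) + lf(k) + lf(tot - k) -
      (lf(tot) + lf(a) + lf(b) + lf(c) + lf(d))
  }, numeric(1))
  p <- exp(logp)
  sum(p[p <= p[support == alt_a] * (1 + 1e-7)])
}

# One-sided upper binomial tail P(X >= x | n, prob) by explicit summation.
oracle_binom_tail <- function(x, n, prob) {
  if (x <= 0) return(1)
  i <- x:n
  sum(exp(lchoose(n, i) + i * log(prob) + (n - i) * log1p(-prob)))
}

# One-sided ("greater") rank-sum p for two small groups by enumerating every
# assignment of the pooled ranks to group 1.
oracle_ranksum_greater_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combs <- utils::combn(length(pooled), length(x))
  stats <- apply(combs, 2, function(ii) sum(r[ii]))
  mean(stats >= obs)
}

oracle_ranksum_less_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combs <- utils::combn(length(pooled), length(x))
  stats <- apply(combs, 2, function(ii) sum(r[ii]))
  mean(stats <= obs)
}

# Build a count table from per-sample (ref, alt) matrices.
make_counts <- function(ref, alt, samples = NULL, gene = NULL, pos = NULL) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  n <- nrow(ref)
  if (is.null(samples))
    samples <- c(paste0("S_ADAR_", seq_len(ncol(ref) / 2)),
                 paste0("EV_", seq_len(ncol(ref) / 2)))
  if (is.null(gene)) gene <- paste0("g", seq_len(n))
  if (is.null(pos)) pos <- seq_len(n) * 10L
  out <- data.frame(site_id = sprintf("s%03d", seq_len(n)), gene = gene,
                    chrom = gene, pos = pos, strand = "+",
                    stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    out[[paste0("ref_", samples[j])]] <- ref[, j]
    out[[paste0("alt_", samples[j])]] <- alt[, j]
  }
  out
}
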