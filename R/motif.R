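#' Extract sense-strand sequence windows around edit sites
#'
#' Cuts a window of `window` bases either side of each edit site out of the
#' contig sequence, clipped at the transcript ends.  Minus-strand sites are
#' reverse-complemented to the sense strand.  Returned sequences are RNA
#' alphabet; `site_offset` gives the 0-based position of the edit site
#' within each returned window.
#'
#' @param calls data frame with `site_id`, `chrom`, `pos`, `strand`,
#'   `gene` and (if annotated) `region`.
#' @param transcripts BED-like transcript intervals (used for clipping).
#' @param sequences named character vector (or `DNAStringSet`) of contig
#'   sequences, DNA alphabet, names matching `chrom`.
#' @param window half-window in bases (default 250).
#' @return data frame `site_id`, `gene`, `region`, `seq` (RNA),
#'   `site_offset`; attribute `window`.  Sites whose contig has no sequence
#'   are skipped with a warning.
#' @export
extract_context_sequences <- function(calls, transcripts, sequences, window = 250) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  missing_seq <- !(calls$chrom %in% names(sequences))
  if (any(missing_seq))
    warning(sprintf("%d site(s) skipped: no sequence for contig", sum(missing_seq)))
  calls <- calls[!missing_seq, , drop = FALSE]
  # transcript extent per contig for clipping
  ext <- tapply(seq_len(nrow(transcripts)), transcripts$chrom, function(i)
    c(min(transcripts$start[i]), max(transcripts$end[i])))
  n <- nrow(calls)
  seqs <- character(n); offs <- integer(n)
  for (i in seq_len(n)) {
    chrom <- calls$chrom[i]; pos <- calls$pos[i]
    full <- sequences[[chrom]]
    bounds <- ext[[chrom]]
    if (is.null(bounds)) bounds <- c(0L, nchar(full))
    lo <- max(bounds[1], pos - window)
    hi <- min(bounds[2], pos + window + 1L)   # half-open
    s <- substr(full, lo + 1L, hi)
    off <- pos - lo
    if (identical(calls$strand[i], "-")) {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      off <- nchar(s) - 1L - off
    }
    seqs[i] <- chartr("T", "U", s)
    offs[i] <- off
  }
  out <- data.frame(site_id = calls$site_id, gene = calls$gene,
                    region = if ("region" %in% names(calls)) calls$region else NA,
                    seq = seqs, site_offset = as.integer(offs),
                    stringsAsFactors = FALSE)
  attr(out, "window") <- window
  out
}

# per-sequence presence counts of all k-mers of length k
kmer_presence <- function(seqs, k) {
  tallies <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  table(unlist(tallies, use.names = FALSE))
}

#' Rank k-mers by enrichment in foreground vs background windows
#'
#' Presence/absence enrichment: for every k-mer (k over `k_range`) occurring
#' in at least one foreground window, the fraction of foreground sequences
#' containing it is tested against the background presence rate with a
#' one-sided binomial tail `P(X >= fg_count | fg_total, bg_rate)`;
#' Benjamini-Hochberg correction is applied across all tested k-mers.
#' Presence (not occurrence) counting avoids sequence-length bias; the
#' background rate is floored at half a count so k-mers never seen in the
#' background do not yield degenerate zero-rate tests.
#'
#' @param fg,bg character vectors of RNA-alphabet windows (foreground:
#'   around edit sites; background: matched windows from non-target
#'   transcripts).  At least 10 of each.
#' @param k_range length-2 integer vector, inclusive k-mer length range.
#' @return data frame of class `motif_ranking`, one row per k-mer:
#'   `kmer`, `k`, `fg_count`, `fg_total`, `bg_count`, `bg_total`,
#'   `enrichment` (presence-rate ratio; background rate floored at half a
#'   count when zero), `p_value`, `q_value`; ranked by `q_value` then
#'   decreasing enrichment.
#' @export
rank_kmers <- function(fg, bg, k_range = c(4, 7)) {
  if (!length(fg)) stop("empty foreground sequence set", call. = FALSE)
  if (length(fg) < 10 || length(bg) < 10)
    stop("need at least 10 foreground and 10 background sequences", call. = FALSE)
  ks <- seq(k_range[1], k_range[2])
  res <- lapply(ks, function(k) {
    fg_tab <- kmer_presence(fg, k)
    bg_tab <- kmer_presence(bg, k)
    kmers <- names(fg_tab)
    fg_count <- as.integer(fg_tab)
    bg_count <- as.integer(bg_tab[kmers]); bg_count[is.na(bg_count)] <- 0L
    # background presence rate floored at half a count: a k-mer never seen
    # in the background would otherwise give a degenerate zero-rate test
    bg_rate <- pmax(bg_count, 0.5) / length(bg)
    p <- stats::pbinom(fg_count - 1L, length(fg), bg_rate, lower.tail = FALSE)
    enr <- (fg_count / length(fg)) / (pmax(bg_count, 0.5) / length(bg))
    data.frame(kmer = kmers, k = k, fg_count = fg_count, fg_total = length(fg),
               bg_count = bg_count, bg_total = length(bg),
               enrichment = enr, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$q_value, -res$enrichment, res$kmer), ]
  rownames(res) <- NULL
  structure(res, class = c("motif_ranking", "data.frame"))
}

#' @export
print.motif_ranking <- function(x, n = 10, ...) {
  cat(sprintf("k-mer enrichment ranking: %d k-mers tested\n", nrow(x)))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

# Expand a motif spec to a regular expression over the RNA alphabet.
# Supports a leading "X/Y" alternative (e.g. "G/AGUAAG" = [GA]GUAAG) and
# IUPAC one-letter ambiguity codes.
motif_regex <- function(motif) {
  motif <- toupper(motif)
  m <- regmatches(motif, regexec("^([ACGU])/([ACGU])(.*)$", motif))[[1]]
  if (length(m)) motif <- paste0("[", m[2], m[3], "]", m[4])
  iupac <- c(R = "[AG]", Y = "[CU]", S = "[GC]", W = "[AU]", K = "[GU]",
             M = "[AC]", B = "[CGU]", D = "[AGU]", H = "[ACU]", V = "[ACG]",
             N = "[ACGU]")
  out <- ""
  i <- 1
  while (i <= nchar(motif)) {
    ch <- substr(motif, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(motif, i, nchar(motif)))
      out <- paste0(out, substr(motif, i, i + j - 1))
      i <- i + j
    } else {
      out <- paste0(out, if (ch %in% names(iupac)) iupac[[ch]] else ch)
      i <- i + 1
    }
  }
  out
}

motif_width <- function(motif) {
  motif <- toupper(motif)
  motif <- sub("^([ACGU])/([ACGU])", "\\1", motif)
  nchar(gsub("\\[[^]]*\\]", "N", motif))
}

#' Signed distances from edit sites to the nearest motif occurrence
#'
#' For each window the motif's occurrences are located (overlapping matches
#' included); the signed distance is motif start minus edit-site offset,
#' and the occurrence nearest in absolute distance is kept (ties resolved
#' to the negative, upstream side).  Sites with no occurrence within
#' `window` bases are excluded and counted.  A Gaussian kernel density
#' (Silverman bandwidth, 501-point grid over +/-`window`, renormalized to
#' unit mass on the grid) summarizes each profile.
#'
#' @param windows output of [extract_context_sequences()].
#' @param motifs character vector of motif specs (exact RNA strings; a
#'   leading `X/Y` alternative and IUPAC codes allowed).
#' @param window maximum absolute distance retained (defaults to the
#'   windows' extraction half-window).
#' @param by_region also compute per-region profiles?
#' @return nested list of class `distance_profiles`: one entry per motif,
#'   each a list of `distance_profile` objects (`all` plus one per region)
#'   with fields `distances`, `n_excluded`, `density` (grid data frame),
#'   `window`, `motif`.
#' @export
nearest_motif_distances <- function(windows, motifs, window = NULL,
                                    by_region = TRUE) {
  if (is.null(window)) window <- attr(windows, "window")
  if (is.null(window)) window <- 250
  out <- lapply(motifs, function(mt) {
    rx <- paste0("(?=", motif_regex(mt), ")")  # lookahead: overlapping hits
    d <- vapply(seq_len(nrow(windows)), function(i) {
      starts <- gregexpr(rx, windows$seq[i], perl = TRUE)[[1]]
      if (starts[1] == -1) return(NA_real_)
      dd <- (starts - 1) - windows$site_offset[i]
      dd <- dd[abs(dd) <= window]
      if (!length(dd)) return(NA_real_)
      dd[order(abs(dd), dd)][1]   # nearest; tie -> upstream (negative)
    }, numeric(1))
    mk_profile <- function(dv) {
      n_exc <- sum(is.na(dv))
      dv <- dv[!is.na(dv)]
      dens <- if (length(dv) >= 2 && stats::sd(dv) > 0) {
        kd <- stats::density(dv, bw = "nrd0", n = 501, from = -window, to = window)
        grid <- data.frame(x = kd$x, y = kd$y)
        integ <- sum(diff(grid$x) * (utils::head(grid$y, -1) + utils::tail(grid$y, -1)) / 2)
        grid$y <- grid$y / integ
        grid
      } else NULL
      structure(list(distances = dv, n_excluded = n_exc, density = dens,
                     window = window, motif = mt),
                class = "distance_profile")
    }
    prof <- list(all = mk_profile(d))
    if (by_region && "region" %in% names(windows)) {
      for (r in unique(stats::na.omit(windows$region)))
        prof[[r]] <- mk_profile(d[windows$region == r])
    }
    if (!length(prof$all$distances))
      warning(sprintf("motif %s: no occurrences within the window", mt))
    prof
  })
  names(out) <- motifs
  structure(out, class = "distance_profiles")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("distance profile for %s: %d sites retained, %d excluded (window +/-%d)\n",
              x$motif, length(x$distances), x$n_excluded, x$window))
  if (length(x$distances))
    cat(sprintf("  median distance %g, IQR [%g, %g]\n",
                stats::median(x$distances),
                stats::quantile(x$distances, 0.25),
                stats::quantile(x$distances, 0.75)))
  invisible(x)
}

#' @method plot distance_profile
#' @export
plot.distance_profile <- function(x, ...) {
  if (is.null(x$density)) {
    warning("no density available (too few distances)")
    return(invisible(x))
  }
  graphics::plot(x$density$x, x$density$y, type = "l",
                 xlab = "distance to nearest motif (bases)",
                 ylab = "density", main = x$motif, ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}
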