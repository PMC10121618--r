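make_seq <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

test_that("context windows clip at transcript ends and honor strand", {
  tx <- data.frame(chrom = "g1", start = c(0, 200, 1100), end = c(200, 1100, 1700),
                   gene = "g1", transcript_id = "t1",
                   region = c("5UTR", "CDS", "3UTR"), strand = "+",
                   stringsAsFactors = FALSE)
  s <- make_seq(1700, 1)
  calls <- data.frame(site_id = "a", chrom = "g1", pos = 1110L, gene = "g1",
                      strand = "+", region = "3UTR", stringsAsFactors = FALSE)
  w <- extract_context_sequences(calls, tx, c(g1 = s), window = 250)
  # left side reaches pos-250, right side full 250: length 501
  expect_identical(nchar(w$seq), 501L)
  expect_identical(w$site_offset, 250L)
  # site 10 bases into the 3'UTR of a transcript starting at 0: clip at 0
  calls2 <- calls; calls2$pos <- 10L
  w2 <- extract_context_sequences(calls2, tx, c(g1 = s), window = 250)
  expect_identical(nchar(w2$seq), 261L)
  expect_identical(w2$site_offset, 10L)
  expect_identical(chartr("U", "T", w2$seq), substr(s, 1, 261))
  # minus strand: reverse complement, offset flipped
  calls3 <- calls; calls3$strand <- "-"
  w3 <- extract_context_sequences(calls3, tx, c(g1 = s), window = 250)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 1110 - 250 + 1, 1110 + 250 + 1))))
  expect_identical(w3$seq, chartr("T", "U", rc))
  expect_identical(w3$site_offset, 250L)
  # missing contig sequence: skipped with a warning
  calls4 <- rbind(calls, within(calls, { site_id <- "b"; chrom <- "gX" }))
  expect_warning(w4 <- extract_context_sequences(calls4, tx, c(g1 = s)), "skipped")
  expect_identical(nrow(w4), 1L)
})

test_that("k-mer enrichment p-values equal the closed-form binomial tail", {
  set.seed(2)
  # 10 of 20 fg sequences carry the 4-mer, background rate 10/50
  fg <- vapply(1:20, function(i) make_seq(60, 100 + i), character(1))
  fg <- chartr("T", "U", fg)
  fg <- vapply(seq_along(fg), function(i) {
    if (i <= 10) paste0(substr(fg[i], 1, 28), "ACGU", substr(fg[i], 33, 60))
    else gsub("ACGU", "ACGA", fg[i], fixed = TRUE)
  }, character(1))
  bg <- vapply(1:50, function(i) make_seq(60, 300 + i), character(1))
  bg <- chartr("T", "U", bg)
  has_bg <- grepl("ACGU", bg, fixed = TRUE)
  res <- rank_kmers(fg, bg, k_range = c(4, 4))
  row <- res[res$kmer == "ACGU", ]
  expect_identical(row$fg_count, 10L)
  expect_identical(row$bg_count, sum(has_bg))
  rate <- max(sum(has_bg), 0.5) / 50
  expect_equal(row$p_value, oracle_binom_tail(10, 20, rate), tolerance = 1e-12)
  expect_error(rank_kmers(fg[1:5], bg), "at least 10")
  expect_error(rank_kmers(character(0), bg), "empty")
})

test_that("fg == bg is a null: enrichments near 1 and no small q-values", {
  set.seed(3)
  seqs <- chartr("T", "U", vapply(1:30, function(i) make_seq(80, 500 + i),
                                  character(1)))
  res <- rank_kmers(seqs, seqs, k_range = c(4, 5))
  shared <- res[res$bg_count > 0, ]
  expect_true(all(shared$enrichment == 1))
  expect_gt(min(res$q_value), 0.5)
})

test_that("planted motif ranks first among k-mers of its length", {
  cfg <- edit_sim_config(n_genes = 150, seed = 23)
  sim <- simulate_edit_dataset(cfg)
  calls <- call_edits(sim$counts, transcripts = sim$transcripts)
  fg <- extract_context_sequences(calls, sim$transcripts, sim$sequences)
  bg <- background_windows(setdiff(unique(sim$counts$gene), calls$gene),
                           sim$transcripts, sim$sequences,
                           n = max(50, nrow(fg)), seed = 99)
  res <- rank_kmers(fg$seq, bg$seq, k_range = c(6, 6))
  expect_identical(res$kmer[1], "ACUUAG")
  # every true-site window contains the planted motif
  truth <- sim$truth[match(fg$site_id, sim$truth$site_id), ]
  expect_true(all(grepl("ACUUAG", fg$seq[truth$is_true_target], fixed = TRUE)))
})

test_that("nearest-distance selection is signed, nearest-by-absolute, ties upstream", {
  # site at offset 50; motif occurrences at starts 10 (d=-40) and 75 (d=+25)
  seqpad <- function(parts) paste(parts, collapse = "")
  base <- strrep("C", 120)
  s <- base
  substr(s, 11, 16) <- "ACUUAG"
  substr(s, 76, 81) <- "ACUUAG"
  w <- data.frame(site_id = "a", gene = "g", region = "3UTR", seq = s,
                  site_offset = 50L, stringsAsFactors = FALSE)
  attr(w, "window") <- 250
  d <- nearest_motif_distances(w, "ACUUAG", by_region = FALSE)
  expect_identical(d$ACUUAG$all$distances, 25)
  # tie at +/-30 resolves to the upstream (negative) side
  s2 <- base
  substr(s2, 21, 26) <- "ACUUAG"
  substr(s2, 81, 86) <- "ACUUAG"
  w2 <- w; w2$seq <- s2
  d2 <- nearest_motif_distances(w2, "ACUUAG", by_region = FALSE)
  expect_identical(d2$ACUUAG$all$distances, -30)
  # site inside a motif occurrence starting at the site: distance 0
  s3 <- base; substr(s3, 51, 56) <- "ACUUAG"
  w3 <- w; w3$seq <- s3
  expect_identical(nearest_motif_distances(w3, "ACUUAG",
                                           by_region = FALSE)$ACUUAG$all$distances, 0)
  # no occurrence: excluded and counted, with a warning
  w4 <- w; w4$seq <- base
  expect_warning(d4 <- nearest_motif_distances(w4, "ACUUAG", by_region = FALSE),
                 "no occurrences")
  expect_identical(d4$ACUUAG$all$n_excluded, 1L)
})

test_that("IUPAC / purine-alternative motifs match both expansions, overlaps included", {
  s <- paste0(strrep("C", 30), "GGUAAG", strrep("C", 20), "AGUAAG", strrep("C", 30))
  w <- data.frame(site_id = "a", gene = "g", region = "CDS", seq = s,
                  site_offset = 0L, stringsAsFactors = FALSE)
  attr(w, "window") <- 100
  d <- nearest_motif_distances(w, "G/AGUAAG", by_region = FALSE)
  expect_identical(d[["G/AGUAAG"]]$all$distances, 30)
  # overlapping occurrences are all found
  s2 <- paste0(strrep("C", 10), "AAAA", strrep("C", 10))
  w2 <- data.frame(site_id = "b", gene = "g", region = "CDS", seq = s2,
                   site_offset = 12L, stringsAsFactors = FALSE)
  attr(w2, "window") <- 50
  d2 <- nearest_motif_distances(w2, "AA", by_region = FALSE)
  expect_identical(d2$AA$all$distances, 0)
})

test_that("distance profile is invariant to padding beyond the search window and its density integrates to 1", {
  cfg <- edit_sim_config(n_genes = 150, seed = 31)
  sim <- simulate_edit_dataset(cfg)
  calls <- call_edits(sim$counts, transcripts = sim$transcripts)
  fg <- extract_context_sequences(calls, sim$transcripts, sim$sequences,
                                  window = 250)
  fg_padded <- fg
  fg_padded$seq <- paste0(fg$seq, strrep("C", 40))  # pad outside the window
  d1 <- nearest_motif_distances(fg, "ACUUAG", window = 200, by_region = FALSE)
  d2 <- nearest_motif_distances(fg_padded, "ACUUAG", window = 200, by_region = FALSE)
  expect_identical(d1$ACUUAG$all$distances, d2$ACUUAG$all$distances)
  grid <- d1$ACUUAG$all$density
  integ <- sum(diff(grid$x) * (head(grid$y, -1) + tail(grid$y, -1)) / 2)
  expect_gt(integ, 0.995); expect_lt(integ, 1.005)
})
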