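test_that("per-sample frequencies and unweighted condition means", {
  counts <- make_counts(ref = rbind(c(10, 14, 10, 5)),
                        alt = rbind(c(3, 6, 0, 5)),
                        samples = c("S_ADAR_1", "S_ADAR_2", "EV_1", "EV_2"))
  fr <- compute_site_frequencies(counts)
  expect_equal(fr$f_adar, (3 / 13 + 6 / 20) / 2)
  expect_equal(fr$f_ev, (0 + 0.5) / 2)
  # spec'd hand arithmetic: 3/10 and 6/20 depth-unweighted
  counts2 <- make_counts(ref = rbind(c(7, 14, 10, 10)),
                         alt = rbind(c(3, 6, 0, 0)),
                         samples = c("S_ADAR_1", "S_ADAR_2", "EV_1", "EV_2"))
  expect_equal(compute_site_frequencies(counts2)$f_adar, 0.3)
  # zero-depth sample excluded; zero-depth condition flagged untestable
  counts3 <- make_counts(ref = rbind(c(10, 0, 0, 0)),
                         alt = rbind(c(5, 0, 0, 0)),
                         samples = c("S_ADAR_1", "S_ADAR_2", "EV_1", "EV_2"))
  fr3 <- compute_site_frequencies(counts3)
  expect_equal(fr3$f_adar, 1 / 3)
  expect_true(is.na(fr3$f_ev))
  expect_false(fr3$testable)
  counts3$ref_EV_1 <- -1L
  expect_error(compute_site_frequencies(counts3), "negative")
})

test_that("pooled Fisher p-values match the enumeration oracle and stats::fisher.test", {
  cases <- list(c(8, 2, 1, 9), c(0, 10, 0, 10), c(5, 5, 5, 5),
                c(12, 0, 0, 12), c(3, 27, 1, 29), c(1, 0, 0, 1))
  for (cs in cases) {
    p_impl <- test_site(alt = c(cs[1], cs[3]), ref = c(cs[2], cs[4]),
                        condition = c("S_ADAR", "EV"))
    expect_equal(p_impl, oracle_fisher_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
    expect_equal(p_impl,
                 stats::fisher.test(matrix(cs, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  # identical pooled counts => p = 1
  expect_equal(test_site(c(4, 4), c(6, 6), c("S_ADAR", "EV")), 1)
  # depth 1 per condition can never reach significance
  expect_gte(test_site(c(1, 0), c(0, 1), c("S_ADAR", "EV")), 0.05)
  # a condition with no coverage is skipped with a warning
  expect_warning(p <- test_site(c(5, 0), c(5, 0), c("S_ADAR", "EV")), "skipped")
  expect_true(is.na(p))
})

test_that("beta-binomial LRT separates strong differences and stays calm under the null", {
  cond <- rep(c("S_ADAR", "EV"), each = 3)
  p_null <- test_site(alt = c(2, 3, 2, 3, 2, 2), ref = rep(97, 6), cond,
                      method = "betabinom_lrt")
  expect_gt(p_null, 0.1)
  p_strong <- test_site(alt = c(40, 45, 38, 1, 0, 2), ref = c(60, 55, 62, 99, 100, 98),
                        cond, method = "betabinom_lrt")
  expect_lt(p_strong, 1e-5)
  expect_lt(p_strong, p_null)
})

test_that("calling applies strict q < alpha AND delta_f > min_delta with a depth floor", {
  # site 1: strong effect (called); site 2: significant but delta 0.09 (not
  # called); site 3: null (not called); site 4: fails the depth filter
  ref <- rbind(c(150, 150, 300, 300),
               c(273, 273, 300, 300),
               c(299, 299, 300, 300),
               c(2, 2, 2, 2))
  alt <- rbind(c(150, 150, 0, 0),
               c(27, 27, 0, 0),
               c(1, 1, 0, 0),
               c(2, 0, 0, 0))
  counts <- make_counts(ref, alt,
                        samples = c("S_ADAR_1", "S_ADAR_2", "EV_1", "EV_2"))
  calls <- call_edits(counts, min_depth = 10)
  expect_identical(calls$site_id, "s001")
  expect_identical(attr(calls, "n_tested"), 3L)
  tested <- attr(calls, "tested")
  expect_equal(tested$delta_f[tested$site_id == "s002"], 0.09, tolerance = 1e-9)
  expect_lt(tested$q_value[tested$site_id == "s002"], 0.05) # fails only on delta
  # empty input is an empty result, not an error
  expect_identical(nrow(call_edits(counts[0, ])), 0L)
  expect_error(call_edits(counts, alpha = 0), "alpha")
})

test_that("BH q-values are a monotone step function within [0,1]", {
  set.seed(42)
  cfg <- edit_sim_config(n_genes = 120, seed = 21)
  sim <- simulate_edit_dataset(cfg)
  calls <- call_edits(sim$counts)
  tested <- attr(calls, "tested")
  ord <- order(tested$p_value)
  q <- tested$q_value[ord]
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q) >= -1e-12))
  expect_equal(q, stats::p.adjust(tested$p_value[ord], "BH"))
})

test_that("mean delta_f estimate is stable under doubled coverage", {
  base <- edit_sim_config(n_genes = 1500, coverage_mean = 100,
                          effect_delta = 0.3, seed = 13)
  dbl <- edit_sim_config(n_genes = 1500, coverage_mean = 200,
                         effect_delta = 0.3, seed = 14)
  d1 <- simulate_edit_dataset(base); d2 <- simulate_edit_dataset(dbl)
  m1 <- mean(compute_site_frequencies(d1$counts)$delta_f[d1$truth$is_true_target])
  m2 <- mean(compute_site_frequencies(d2$counts)$delta_f[d2$truth$is_true_target])
  expect_lt(abs(m1 - m2), 0.01)
})

test_that("region annotation uses the 3UTR > CDS > 5UTR priority", {
  tx <- data.frame(chrom = "chr1",
                   start = c(0, 200, 1100, 900),
                   end = c(200, 1100, 1700, 1400),
                   gene = "gA",
                   transcript_id = c("t1", "t1", "t1", "t2"),
                   region = c("5UTR", "CDS", "3UTR", "3UTR"),
                   strand = "+", stringsAsFactors = FALSE)
  tx$region[4] <- "3UTR"  # isoform 2 3'UTR overlapping isoform 1 CDS
  calls <- data.frame(site_id = c("a", "b", "c", "d"), chrom = "chr1",
                      pos = c(1200, 1000, 100, 5000), gene = "gA",
                      stringsAsFactors = FALSE)
  ann <- annotate_sites(calls, tx)
  expect_identical(ann$region, c("3UTR", "3UTR", "5UTR", "other"))
  expect_identical(ann$gene[4], "gA")  # input gene retained off-transcript
})

test_that("gene-level summary counts sites and partitions cross-dataset sets", {
  calls <- structure(data.frame(site_id = c("s1", "s2", "s3"),
                                gene = c("gA", "gA", "gB"),
                                q_value = c(0.01, 0.02, 0.03),
                                delta_f = c(0.5, 0.4, 0.3),
                                stringsAsFactors = FALSE),
                     class = c("edit_calls", "data.frame"))
  calls2 <- structure(data.frame(site_id = "s9", gene = "gB",
                                 q_value = 0.01, delta_f = 0.2,
                                 stringsAsFactors = FALSE),
                      class = c("edit_calls", "data.frame"))
  ts <- summarize_targets(calls, calls2, names = c("HSC", "MPP"))
  gA <- ts$genes[ts$genes$gene == "gA", ]
  expect_identical(gA$n_edit_sites, 2L)
  expect_equal(gA$best_q, 0.01)
  expect_identical(unname(ts$sets$counts),
                   c(1L, 1L, 0L))  # shared gB, HSC-unique gA, MPP-unique none
  # |A| = shared + unique identity
  expect_identical(length(ts$sets$shared) + length(ts$sets$unique1),
                   nrow(ts$genes))
})

test_that("synthetic data reproduce 3'UTR-dominant editing with 1-2 sites per gene", {
  cfg <- edit_sim_config(n_genes = 400, sites_per_gene = 1.5, seed = 17)
  sim <- simulate_edit_dataset(cfg)
  calls <- call_edits(sim$counts, transcripts = sim$transcripts)
  reg <- table(calls$region)
  expect_gt(reg[["3UTR"]], reg[["CDS"]])
  ts <- summarize_targets(calls)
  expect_true(names(which.max(ts$site_histogram)) %in% c("1", "2"))
})
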