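test_that("boundary semantics: 2-fold and log2FC 0.6 inclusive for pairs, strict for polarity", {
  # ratio exactly 2 is asymmetric (inclusive)
  expect_identical(classify_numb_pair(100, 50, high_threshold = 60), "asymmetric")
  expect_identical(classify_numb_pair(100, 50.0001, 60), "symmetric_commitment")
  # log2 ratio exactly 0.6 is asymmetric for pair scoring (inclusive)
  expect_identical(classify_log2fc_pair(100, 100 * 2^0.6, high_threshold = 50),
                   "asymmetric")
  expect_identical(classify_log2fc_pair(100, 140, high_threshold = 50),
                   "symmetric_high")   # log2(1.4) = 0.485 < 0.6
  # log2 ratio exactly 0.6 is NOT polar (strict >)
  expect_identical(score_polarity(100, 100 * 2^0.6), "unpolarized")
  expect_identical(score_polarity(100, 160), "polar")  # log2(1.6) = 0.678
  expect_identical(score_polarity(100, 100), "unpolarized")
})

test_that("pair classification splits symmetric pairs by mean against the threshold", {
  expect_identical(classify_numb_pair(80, 80, 50), "symmetric_commitment")
  expect_identical(classify_numb_pair(10, 12, 50), "symmetric_renewal")
  expect_identical(classify_log2fc_pair(10, 12, high_threshold = 50),
                   "symmetric_low")
  expect_error(classify_numb_pair(-1, 10, 50), "positive")
  expect_error(score_polarity(0, 10), "positive")
})

test_that("classifiers are scale invariant and symmetric in daughter labels", {
  set.seed(20)
  i1 <- stats::rlnorm(200, 4, 1); i2 <- stats::rlnorm(200, 4, 1)
  for (c_scale in c(0.1, 3, 42)) {
    a <- classify_numb_pair(i1, i2, 55) == "asymmetric"
    b <- classify_numb_pair(c_scale * i1, c_scale * i2, 55 * c_scale) == "asymmetric"
    expect_identical(a, b)
    expect_identical(score_polarity(i1, i2), score_polarity(c_scale * i1, c_scale * i2))
    expect_identical(classify_log2fc_pair(i1, i2, high_threshold = 55) == "asymmetric",
                     classify_log2fc_pair(c_scale * i1, c_scale * i2,
                                          high_threshold = 55 * c_scale) == "asymmetric")
  }
  expect_identical(classify_numb_pair(i1, i2, 55) == "asymmetric",
                   classify_numb_pair(i2, i1, 55) == "asymmetric")
  expect_identical(classify_log2fc_pair(i1, i2, high_threshold = 55) == "asymmetric",
                   classify_log2fc_pair(i2, i1, high_threshold = 55) == "asymmetric")
  expect_identical(score_polarity(i1, i2), score_polarity(i2, i1))
})

test_that("confusion matrix is exactly diagonal on noiseless generator output", {
  prs <- simulate_daughter_pairs(600, mix = c(0.4, 0.3, 0.3), noise_cv = 0,
                                 seed = 12)
  pred <- classify_numb_pair(prs$i1, prs$i2, 100)
  map <- c(sym_renewal = "sym_renewal", sym_commitment = "sym_commitment",
           asymmetric = "asymmetric")
  pred_mapped <- c(asymmetric = "asymmetric",
                   symmetric_commitment = "sym_commitment",
                   symmetric_renewal = "sym_renewal")[pred]
  expect_identical(unname(pred_mapped), prs$true_class)
  cells <- simulate_polarity_cells(400, frac_polar = 0.5, noise_sd = 0, seed = 12)
  expect_identical(score_polarity(cells$h1, cells$h2) == "polar",
                   cells$true_polar)
})

test_that("co-segregation concordance tracks the generator probability", {
  prs <- simulate_daughter_pairs(500, mix = c(0.2, 0.2, 0.6), noise_cv = 0.02,
                                 coseg_prob = 0.8, seed = 33)
  prs$class1 <- classify_numb_pair(prs$i1, prs$i2, 100)
  prs$class2 <- classify_numb_pair(prs$j1, prs$j2, 100)
  cs <- cosegregation_table(prs)
  expect_identical(dim(cs$table), c(3L, 3L))
  expect_gt(cs$n_double_asymmetric, 100)
  expect_lt(abs(cs$concordance - 0.8), 0.05)
  # perfectly shared intensities: concordance 1; swapped daughters: 0
  p2 <- data.frame(class1 = rep("asymmetric", 10), class2 = rep("asymmetric", 10),
                   i1 = 1:10 * 10, i2 = rep(5, 10))
  p2$j1 <- p2$i1; p2$j2 <- p2$i2
  expect_equal(cosegregation_table(p2)$concordance, 1)
  p3 <- p2; p3$j1 <- p2$j2; p3$j2 <- p2$j1
  expect_equal(cosegregation_table(p3)$concordance, 0)
  p4 <- p2; p4$class2 <- "symmetric_low"
  expect_message(cs4 <- cosegregation_table(p4), "undefined")
  expect_true(is.na(cs4$concordance))
})

test_that("division summary averages replicate fractions and tests across genotypes", {
  set.seed(7)
  mk <- function(geno, mix, reps = 5, n = 100) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      p <- simulate_daughter_pairs(n, mix = mix, noise_cv = 0.02,
                                   genotype = geno, replicate = r,
                                   seed = 1000 * r + nchar(geno))
      classify_pairs(p, rule = "numb", high_threshold = 100)
    }))
  }
  pairs <- rbind(mk("WT", c(0.5, 0.25, 0.25)), mk("KO", c(0.2, 0.3, 0.5)))
  ds <- summarize_divisions(pairs)
  sums <- tapply(ds$fractions$mean_fraction, ds$fractions$genotype, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_false(is.null(ds$tests))
  asym <- ds$tests[ds$tests$category == "asymmetric", ]
  expect_lt(asym$p_value, 0.05)  # 0.25 vs 0.5 over 5 replicates
  # single replicate: fractions only, tests skipped with a notice
  one <- classify_pairs(simulate_daughter_pairs(50, genotype = "WT", seed = 2),
                        rule = "numb", high_threshold = 100)
  two <- classify_pairs(simulate_daughter_pairs(50, genotype = "KO", seed = 3),
                        rule = "numb", high_threshold = 100)
  expect_message(ds1 <- summarize_divisions(rbind(one, two)), "skipped")
  expect_null(ds1$tests)
  expect_true(all(ds1$fractions$sem == 0))
})

test_that("auto threshold is the per-replicate median of pair means", {
  pairs <- data.frame(pair_id = paste0("p", 1:6), genotype = "WT",
                      replicate = rep(1:2, each = 3),
                      i1 = c(10, 20, 30, 100, 200, 300),
                      i2 = c(10, 20, 30, 100, 200, 300))
  thr <- auto_high_threshold(pairs)
  expect_equal(unname(thr), c(20, 200))
  cls <- classify_pairs(pairs, rule = "numb", high_threshold = "auto")
  expect_identical(cls$class,
                   rep(c("symmetric_renewal", "symmetric_commitment",
                         "symmetric_commitment"), 2))
})
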