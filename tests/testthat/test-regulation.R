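test_that("median-of-ratios size factors match the direct oracle", {
  m <- matrix(rep(c(10, 20, 30, 40), 4), ncol = 4)
  expect_equal(unname(size_factors(m)), rep(1, 4))

  m2 <- m
  m2[, 3] <- m2[, 3] * 2
  f <- size_factors(m2)
  expect_equal(unname(f[3] / f[1]), 2)

  set.seed(91)
  m3 <- matrix(rpois(400, 60) + 1, ncol = 4)
  expect_equal(unname(size_factors(m3)), unname(size_factor_oracle(m3)),
               tolerance = 1e-12)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(93)
  m <- matrix(rnbinom(600, mu = 100, size = 5) + 1, ncol = 6)
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # reference takes the median on the log scale; agreement to ~1%
  expect_equal(unname(ours), unname(ref), tolerance = 0.01)
})

test_that("paired LFC is antisymmetric and recovers large fold changes", {
  set.seed(95)
  wt <- matrix(rpois(300, 200), ncol = 3,
               dimnames = list(sprintf("t%03d", 1:100), NULL))
  f1 <- list(ko = rep(1, 3), wt = rep(1, 3))
  expect_equal(unname(paired_lfc(wt, wt, f1)), rep(0, 100))

  ko <- wt * 4L
  lfc <- paired_lfc(ko, wt, f1)
  expect_true(all(abs(lfc - 2) < 0.05))  # pseudocount-negligible at high counts

  expect_equal(paired_lfc(ko, wt, f1), -paired_lfc(wt, ko, f1))
  expect_error(paired_lfc(wt[, 1:2], wt, f1), "identical shape")
})

test_that("KS shift statistics equal the brute-force CDF-gap oracle", {
  lfc <- c(rep(0, 10), rep(1, 10))
  cls <- c(rep("stringent", 10), rep("non_target", 10))
  res <- cdf_shift_test(setNames(lfc, paste0("t", 1:20)), cls)
  row <- res$tests[res$tests$class_a == "stringent", ]
  expect_equal(row$ks_d, 1)  # disjoint supports

  # identical samples -> D = 0, p = 1
  same <- cdf_shift_test(setNames(rep(seq(0.1, 1, 0.1), 2), paste0("t", 1:20)),
                         cls)
  expect_equal(same$tests$ks_d[1], 0)
  expect_equal(same$tests$ks_p[1], 1)

  # random instances vs max-gap oracle
  set.seed(97)
  for (i in 1:10) {
    a <- rnorm(50)
    b <- rnorm(50, 0.3)
    got <- cdf_shift_test(setNames(c(a, b), paste0("t", 1:100)),
                          c(rep("high", 50), rep("non_target", 50)))
    expect_equal(got$tests$ks_d[1], ks_d_oracle(a, b), tolerance = 1e-12)
  }

  # undersized class skipped with warning
  expect_warning(
    cdf_shift_test(setNames(rnorm(8), paste0("t", 1:8)),
                   c(rep("stringent", 3), rep("non_target", 5))),
    "skipped")
})

test_that("matched controls reproduce the target length distribution", {
  sim <- simulate_experiment(sim_config(n_genes = 3000, seed = 47))
  len <- setNames(sim$txome$length, sim$txome$transcript_id)
  # targets biased toward long transcripts to make matching non-trivial
  ord <- names(sort(len, decreasing = TRUE))
  targets <- ord[seq(1, 600, by = 3)]
  pool <- setdiff(sim$txome$transcript_id, targets)
  mc <- sample_matched_controls(targets, pool, sim$txome, seed = 7)
  expect_length(mc$controls, length(targets))
  expect_length(intersect(mc$controls, targets), 0)
  ks <- suppressWarnings(ks.test(len[mc$targets_used], len[mc$controls]))
  expect_gt(ks$p.value, 0.05)
  # deterministic under seed
  mc2 <- sample_matched_controls(targets, pool, sim$txome, seed = 7)
  expect_identical(mc$controls, mc2$controls)

  # exact-duplicate pool reproduces the length multiset
  tx <- flat_txome(40)
  tx$length <- rep(c(500L, 1000L, 2000L, 4000L), each = 10)
  tx$cds_start <- 0L
  tx$cds_end <- tx$length - 10L
  tx$cds_length <- tx$cds_end - tx$cds_start
  t_ids <- tx$transcript_id[seq(1, 40, by = 2)]
  p_ids <- tx$transcript_id[seq(2, 40, by = 2)]
  mc3 <- sample_matched_controls(t_ids, p_ids, tx, seed = 1)
  expect_equal(sort(tx$length[match(mc3$controls, tx$transcript_id)]),
               sort(tx$length[match(t_ids, tx$transcript_id)]))
})

test_that("abundance matching filters to the stated RPKM range", {
  sim <- simulate_experiment(sim_config(n_genes = 3000, seed = 49))
  ab <- mean_ab <- tapply(sim$abundance$rpkm[sim$abundance$condition == "WT"],
                          sim$abundance$transcript_id[sim$abundance$condition == "WT"],
                          mean)
  ids <- names(ab)
  targets <- ids[seq(1, 400)]
  pool <- setdiff(ids, targets)
  suppressMessages(
    mc <- sample_matched_controls(targets, pool, sim$txome,
                                  abundance = setNames(as.numeric(ab), ids),
                                  match_length = FALSE, match_abundance = TRUE,
                                  abundance_range = c(10, 200), seed = 11))
  used_ab <- as.numeric(ab[mc$targets_used])
  ctrl_ab <- as.numeric(ab[mc$controls])
  expect_true(all(used_ab >= 10 & used_ab <= 200))
  expect_true(all(ctrl_ab >= 10 & ctrl_ab <= 200))
  expect_lt(length(mc$targets_used), length(targets))  # out-of-range excluded
})

test_that("gene-set comparison uses the exact Wilcoxon path on small samples", {
  v <- setNames(c(1, 2, 3, 4, 5, 6), paste0("t", 1:6))
  res <- geneset_compare(v, paste0("t", 1:3), paste0("t", 4:6))
  expect_equal(res$p, 0.1, tolerance = 1e-12)  # exact two-sided

  # identical value multisets -> p = 1
  v2 <- setNames(rep(2, 10), paste0("t", 1:10))
  expect_warning(res2 <- geneset_compare(v2, paste0("t", 1:5), paste0("t", 6:10)),
                 "tied")
  expect_equal(res2$p, 1)

  # large shifted samples -> tiny p
  set.seed(99)
  v3 <- setNames(c(rnorm(300, 1), rnorm(300)), paste0("t", 1:600))
  res3 <- geneset_compare(v3, paste0("t", 1:300), paste0("t", 301:600))
  expect_lt(res3$p, 1e-6)

  expect_error(geneset_compare(v, paste0("t", 1:2), paste0("t", 4:6)), ">= 3")
})

test_that("discrimination index handles exclusions and boundary cases", {
  expect_equal(discrimination_index(30, 30), 0, ignore_attr = TRUE)
  expect_equal(discrimination_index(12, 0), 1, ignore_attr = TRUE)
  expect_equal(discrimination_index(60, 40), 0.2, ignore_attr = TRUE)
  di <- discrimination_index(c(60, 2), c(40, 1))
  expect_true(is.na(di[2]))           # total 3 s < 5 s exclusion
  expect_true(attr(di, "excluded")[2])
  expect_error(discrimination_index(-1, 5), ">= 0")
})
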