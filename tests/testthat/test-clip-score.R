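test_that("coding-region RPKM follows the subtraction formula with sentinels", {
  tx <- data.frame(transcript_id = c("t1", "t2", "t3"), gene_id = paste0("g", 1:3),
                   length = 3000L, cds_start = 0L, cds_end = 2000L,
                   cds_length = 2000L, stringsAsFactors = FALSE)
  # library totals come from the table itself; pad with a bulk transcript
  pos <- c(20L, 3L, 0L)
  neg <- c(0L, 5L, 0L)
  # filler makes (total_cre_pos - total_cre_neg) exactly 2e6
  filler_pos <- 2000000L - sum(pos) + sum(neg)
  tx <- rbind(tx, data.frame(transcript_id = "bulk", gene_id = "gb",
                             length = 3000L, cds_start = 0L, cds_end = 2000L,
                             cds_length = 2000L))
  cnt <- toy_counts(tx, c(pos, filler_pos), c(neg, 0L))
  rpkm <- compute_cds_rpkm(cnt, tx, "rep1")
  # (20 - 0) * 1e9 / (2000 * 2e6) = 5.0
  expect_equal(unname(rpkm["t1"]), 5.0)
  expect_equal(unname(rpkm["t2"]), 1)  # cre_neg >= cre_pos -> sentinel
  expect_equal(unname(rpkm["t3"]), 1)  # no reads in either sample -> sentinel

  # background library deeper than signal -> error
  cnt_bad <- toy_counts(tx, c(1L, 1L, 1L, 1L), c(10L, 10L, 10L, 10L))
  expect_error(compute_cds_rpkm(cnt_bad, tx, "rep1"), "exceed")
})

test_that("abundance regression matches the closed-form normal equations", {
  # collinear input: y = 2x + 1 exactly
  ab <- 2^seq(1, 5)
  clip <- 2^(2 * seq(1, 5) + 1)
  names(ab) <- names(clip) <- paste0("t", 1:5)
  cre <- setNames(rep(5, 5), names(ab))
  fit <- suppressWarnings(fit_abundance_regression(clip, ab, "rep1", cre))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # random instances vs brute-force normal-equation oracle
  set.seed(101)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    ab_i <- setNames(2^runif(n, -2, 8), paste0("t", seq_len(n)))
    clip_i <- setNames(2^(0.9 * log2(ab_i) + rnorm(n, 0, 0.7)), names(ab_i))
    fit_i <- fit_abundance_regression(clip_i, ab_i, "r", setNames(rep(1, n), names(ab_i)))
    oracle <- ols_oracle(log2(ab_i), log2(clip_i))
    expect_equal(fit_i$slope, unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(fit_i$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
  }

  # fewer than 3 fit points -> error
  expect_error(
    fit_abundance_regression(clip[1:2], ab[1:2], "r", cre[1:2]),
    "fewer than 3")
})

test_that("CLIP scores are residuals from the fitted line", {
  fit <- structure(list(replicate_id = "r", slope = 1, intercept = 0,
                        r_squared = 1, n_fit = 10), class = "clip_fit")
  ab <- setNames(c(8, 4, 8), c("a", "b", "c"))
  clip <- setNames(c(8, 8, 1), c("a", "b", "c"))
  sc <- compute_clip_scores(clip, fit, ab)
  expect_equal(unname(sc["a"]), 0)    # exactly on the line
  expect_equal(unname(sc["b"]), 1)    # 2x the fitted value -> +1
  expect_equal(unname(sc["c"]), -3)   # sentinel RPKM 1, abundance 8

  # non-positive abundance propagates as missing
  ab2 <- setNames(c(8, 0), c("a", "b"))
  expect_warning(sc2 <- compute_clip_scores(clip[1:2], fit, ab2), "abundance")
  expect_true(is.na(sc2["b"]))
})

test_that("classification maps the full score grid to classes exactly", {
  vals <- c(-1, 0, 0.5, 1, 1.5, 2, 2.5)
  grid <- expand.grid(r1 = vals, r2 = vals, r3 = vals)
  m <- as.matrix(grid)
  rownames(m) <- sprintf("t%03d", seq_len(nrow(m)))
  got <- aggregate_and_classify(m)
  mean_s <- rowMeans(m)
  expected <- ifelse(apply(m >= 2, 1, all), "stringent",
              ifelse(mean_s >= 1, "high",
              ifelse(mean_s >= 0, "low", "non_target")))
  expect_equal(as.character(got$target_class), unname(expected))

  # worked examples for the class boundaries
  ex <- rbind(c(2.5, 2.1, 3.0), c(3.5, 1.5, 0.5), c(0.2, 0.4, 0.6))
  rownames(ex) <- c("s", "h", "l")
  expect_equal(as.character(aggregate_and_classify(ex)$target_class),
               c("stringent", "high", "low"))

  # any missing replicate -> non_target with flag
  ex_na <- rbind(c(2.5, NA, 3))
  rownames(ex_na) <- "m"
  got_na <- aggregate_and_classify(ex_na)
  expect_equal(as.character(got_na$target_class), "non_target")
  expect_true(got_na$has_missing)
  expect_error(aggregate_and_classify(matrix(numeric(0), 0, 3)), "empty")
})

test_that("scores are depth-invariant and monotone in signal counts", {
  sim <- simulate_experiment(sim_config(n_genes = 300, seed = 17))
  res <- clip_score_pipeline(sim$counts, sim$abundance, sim$txome)

  # multiply one replicate's counts (and hence totals) by a constant
  cnt2 <- sim$counts
  r1 <- cnt2$replicate == "rep1"
  cnt2$cds_count[r1] <- cnt2$cds_count[r1] * 7L
  cnt2$full_count[r1] <- cnt2$full_count[r1] * 7L
  res2 <- clip_score_pipeline(cnt2, sim$abundance, sim$txome)
  expect_equal(res2$scores[, "rep1"], res$scores[, "rep1"], tolerance = 1e-9)

  # OLS property: mean residual over the fitting subset is 0
  pos <- count_matrix(sim$counts, sim$txome, "cre_pos")
  fit_mask <- pos[, "rep1"] >= 1
  expect_lt(abs(mean(res$scores[fit_mask, "rep1"])), 1e-9)

  # monotonicity: raising cre_pos for one transcript raises its score
  tx_up <- sim$txome$transcript_id[which(pos[, "rep1"] > 20)[1]]
  cnt3 <- sim$counts
  sel <- cnt3$transcript_id == tx_up & cnt3$replicate == "rep1" &
    cnt3$library == "cre_pos"
  cnt3$cds_count[sel] <- cnt3$cds_count[sel] + 50L
  rpkm_a <- compute_cds_rpkm(sim$counts, sim$txome, "rep1")
  rpkm_b <- compute_cds_rpkm(cnt3, sim$txome, "rep1")
  expect_gt(rpkm_b[tx_up], rpkm_a[tx_up])

  # classification is total: every transcript gets exactly one class
  expect_false(anyNA(res$table$target_class))
})

test_that("replicate CPM correlation has unit diagonal and scale invariance", {
  tx <- flat_txome(1000)
  set.seed(23)
  base <- rpois(1000, 50)
  cnt <- rbind(
    data.frame(transcript_id = tx$transcript_id, replicate = "rep1",
               library = "cre_pos", cds_count = base, full_count = base),
    data.frame(transcript_id = tx$transcript_id, replicate = "rep2",
               library = "cre_pos", cds_count = 2L * base,
               full_count = 2L * base),
    data.frame(transcript_id = tx$transcript_id, replicate = "rep3",
               library = "cre_pos", cds_count = rpois(1000, 50),
               full_count = 50L)
  )
  r2 <- replicate_correlation(cnt, tx)
  expect_equal(diag(r2), setNames(rep(1, 3), paste0("rep", 1:3)))
  expect_equal(r2, t(r2))
  # exact 2x scaling -> R^2 = 1 (CPM removes depth)
  expect_equal(unname(r2["rep1", "rep2"]), 1, tolerance = 1e-12)
  # independent counts -> near zero
  expect_lt(unname(r2["rep1", "rep3"]), 0.05)
})

test_that("windowed abundance truncates to transcript length and matches uniform coverage", {
  tx <- flat_txome(50, length = 3000L, cds_start = 500L, cds_end = 2500L)
  tx <- rbind(tx, data.frame(transcript_id = "tiny", gene_id = "gt",
                             length = 400L, cds_start = 0L, cds_end = 300L,
                             cds_length = 300L))
  tags <- simulate_uniform_coverage(tx, 400, 30, seed = 31,
                                    replicate = "rep1", library = "trap")
  wa <- windowed_abundance(tags, tx, window_nt = 1000, anchor = "start")
  full_cnt <- table(factor(tags$transcript_id, levels = tx$transcript_id))
  full_rpkm <- as.numeric(full_cnt) * 1e9 / (tx$length * nrow(tags))
  # uniform coverage: windowed RPKM tracks full-transcript RPKM
  ratio <- wa$rpkm / full_rpkm
  expect_lt(abs(median(ratio) - 1), 0.1)
  # transcript shorter than the window: denominator is its full length
  expect_equal(wa$rpkm[wa$transcript_id == "tiny"],
               unname(as.numeric(full_cnt["tiny"])) * 1e9 / (400 * nrow(tags)))

  # reads confined beyond the window -> zero windowed abundance
  far <- data.frame(transcript_id = tx$transcript_id[1], start = 2000L,
                    end = 2030L, replicate = "rep1", library = "trap")
  wa2 <- windowed_abundance(far, tx, window_nt = 1000, anchor = "start")
  expect_equal(wa2$rpkm[wa2$transcript_id == tx$transcript_id[1]], 0)
})
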