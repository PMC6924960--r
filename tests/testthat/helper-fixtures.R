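# small fixtures built in code; all coordinates 0-based half-open

toy_txome <- function() {
  data.frame(
    transcript_id = c("txA", "txB", "txC"),
    gene_id = c("g1", "g2", "g3"),
    length = c(1000L, 2000L, 1500L),
    cds_start = c(100L, 500L, 0L),
    cds_end = c(700L, 1500L, 900L),
    cds_length = c(600L, 1000L, 900L),
    stringsAsFactors = FALSE
  )
}

# long count table from per-transcript cre_pos / cre_neg vectors (one replicate)
toy_counts <- function(txome, pos, neg, replicate = "rep1") {
  rbind(
    data.frame(transcript_id = txome$transcript_id, replicate = replicate,
               library = "cre_pos", cds_count = pos, full_count = pos,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = txome$transcript_id, replicate = replicate,
               library = "cre_neg", cds_count = neg, full_count = neg,
               stringsAsFactors = FALSE)
  )
}

toy_abundance <- function(txome, rpkm, condition = "WT", replicate = "rep1") {
  data.frame(transcript_id = txome$transcript_id, condition = condition,
             replicate = replicate, rpkm = rpkm,
             cds_count = round(rpkm * txome$cds_length / 1e3),
             stringsAsFactors = FALSE)
}

# uniform-structure transcriptome: n identical transcripts
flat_txome <- function(n = 200, length = 1200L, cds_start = 500L,
                       cds_end = 1100L) {
  data.frame(
    transcript_id = sprintf("t%04d", seq_len(n)),
    gene_id = sprintf("g%04d", seq_len(n)),
    length = length, cds_start = cds_start, cds_end = cds_end,
    cds_length = cds_end - cds_start,
    stringsAsFactors = FALSE
  )
}

# closed-form simple-OLS oracle via explicit normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# brute-force NB/Poisson upper tail by term-wise pmf summation
nb_tail_oracle <- function(observed, mu, alpha, tol = 1e-15) {
  pmf <- function(k) {
    if (alpha == 0) return(dpois(k, mu))
    dnbinom(k, mu = mu, size = 1 / alpha)
  }
  # sum P(X < observed) term by term, return 1 - that (exact complement)
  if (observed == 0) return(1)
  1 - sum(pmf(0:(observed - 1)))
}

# brute-force BH step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# brute-force two-sample KS D: max CDF gap over pooled points
ks_d_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# direct median-of-ratios oracle
size_factor_oracle <- function(m) {
  gm <- exp(rowMeans(log(m)))
  ok <- is.finite(gm) & gm > 0
  apply(m, 2, function(cnt) median(cnt[ok] / gm[ok]))
}

# unique scratch path for a named fixture file
scratch_file <- function(name) {
  d <- tempfile("fix")
  dir.create(d)
  file.path(d, name)
}

# row-wise sample variance (test-side copy, independent of package internals)
row_vars_test <- function(m) apply(m, 1, stats::var)
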