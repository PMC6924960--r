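#' CLIP score computation and target classification
#'
#' The CLIP score quantifies binding of an RNA-binding protein to a
#' transcript relative to similarly expressed transcripts. Per replicate j,
#' the background-subtracted coding-region RPKM is
#' \deqn{RPKM_{ij} = \frac{(CrePos_{ij} - CreNeg_{ij}) \times 10^9}
#'   {L^{CDS}_i \, (TotalCrePos_j - TotalCreNeg_j)}}
#' with the sentinel value 1 when the background count is at least the signal
#' count or both are zero. A per-replicate ordinary least-squares regression
#' of log2 CLIP RPKM on log2 abundance RPKM (over transcripts with at least
#' one Cre-positive coding-region tag) gives slope and intercept; the score
#' is the residual
#' \deqn{score_{ij} = \log_2 RPKM_{ij} - (slope_j \log_2 A_i + intercept_j)}
#' computed for every transcript. Transcripts are classified from the
#' replicate scores: stringent (score >= `stringent_min` in all replicates),
#' high (mean >= `high_min`), low (mean in \[0, `high_min`)), else
#' non-target.
#'
#' @name clip-score
NULL

#' Background-subtracted coding-region RPKM for one replicate
#'
#' @param counts long count table with `cre_pos` and `cre_neg` libraries
#' @param txome transcriptome data frame
#' @param replicate replicate identifier
#' @return named numeric vector of RPKM, one entry per transcript in `txome`;
#'   entries where the Cre-negative count is >= the Cre-positive count (or
#'   both are zero) carry the sentinel value 1
#' @export
compute_cds_rpkm <- function(counts, txome, replicate) {
  validate_transcriptome(txome)
  pos <- count_matrix(counts, txome, "cre_pos", "cds")
  neg <- count_matrix(counts, txome, "cre_neg", "cds")
  if (!replicate %in% colnames(pos))
    stop_contract("no cre_pos counts for replicate ", replicate)
  p <- pos[, replicate]
  ng <- if (replicate %in% colnames(neg)) neg[, replicate] else
    setNames(rep(0L, nrow(txome)), txome$transcript_id)
  total_pos <- sum(as.numeric(p))
  total_neg <- sum(as.numeric(ng))
  if (total_pos <= total_neg)
    stop_contract("total cre_pos (", total_pos, ") must exceed total cre_neg (",
                  total_neg, ") for replicate ", replicate)
  rpkm <- (as.numeric(p) - as.numeric(ng)) * 1e9 /
    (as.numeric(txome$cds_length) * (total_pos - total_neg))
  rpkm[ng >= p] <- 1
  setNames(rpkm, txome$transcript_id)
}

# abundance table -> per-transcript mean RPKM vector for one condition
mean_abundance <- function(abundance, condition = "WT") {
  ab <- abundance
  if ("condition" %in% names(ab))
    ab <- ab[ab$condition == condition, , drop = FALSE]
  v <- tapply(ab$rpkm, ab$transcript_id, mean)
  setNames(as.numeric(v), names(v))
}

#' Fit the per-replicate abundance regression
#'
#' OLS of log2 CLIP RPKM on log2 abundance RPKM over transcripts with at
#' least one Cre-positive coding-region tag. Transcripts whose RPKM
#' collapsed to the sentinel 1 can be kept in the fit (default) or excluded
#' via `include_sentinel = FALSE`; transcripts with non-positive abundance
#' are excluded with a logged count.
#'
#' @param clip_rpkm named RPKM vector from [compute_cds_rpkm()]
#' @param abundance abundance table (or named per-transcript RPKM vector)
#' @param replicate replicate identifier (metadata only)
#' @param cre_pos_counts named Cre-positive CDS count vector defining the
#'   fitting filter (>= 1 tag)
#' @param include_sentinel keep sentinel-RPKM transcripts in the fit?
#' @return a `clip_fit` list: `replicate_id`, `slope`, `intercept`,
#'   `r_squared`, `n_fit`
#' @export
fit_abundance_regression <- function(clip_rpkm, abundance, replicate,
                                     cre_pos_counts,
                                     include_sentinel = TRUE) {
  ab <- if (is.data.frame(abundance)) mean_abundance(abundance, "WT") else abundance
  ab <- ab[names(clip_rpkm)]
  cre_pos_counts <- cre_pos_counts[names(clip_rpkm)]
  fit_mask <- !is.na(cre_pos_counts) & cre_pos_counts >= 1
  if (!include_sentinel) fit_mask <- fit_mask & clip_rpkm != 1
  bad_ab <- fit_mask & (is.na(ab) | ab <= 0)
  if (any(bad_ab)) {
    clip_log("fit_abundance_regression: excluded ", sum(bad_ab),
             " fit transcript(s) with non-positive abundance")
    fit_mask <- fit_mask & !bad_ab
  }
  n_fit <- sum(fit_mask)
  if (n_fit < 3)
    stop_contract("fit_abundance_regression: fewer than 3 transcripts pass ",
                  "the fitting filter (", n_fit, ")")
  x <- log2(ab[fit_mask])
  y <- log2(clip_rpkm[fit_mask])
  fit <- lm(y ~ x)
  structure(list(
    replicate_id = replicate,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    n_fit = n_fit
  ), class = "clip_fit")
}

#' Per-transcript CLIP scores for one replicate
#'
#' Residual of log2 CLIP RPKM from the fitted abundance regression, computed
#' for every transcript regardless of whether it had CLIP tags. Transcripts
#' with non-positive or missing abundance get `NA` with a warning.
#'
#' @param clip_rpkm named RPKM vector
#' @param fit a `clip_fit` from [fit_abundance_regression()]
#' @param abundance abundance table or named RPKM vector
#' @return named numeric score vector
#' @export
compute_clip_scores <- function(clip_rpkm, fit, abundance) {
  ab <- if (is.data.frame(abundance)) mean_abundance(abundance, "WT") else abundance
  ab <- ab[names(clip_rpkm)]
  score <- log2(clip_rpkm) - (fit$slope * log2(ab) + fit$intercept)
  undef <- is.na(ab) | ab <= 0
  if (any(undef)) {
    warning(sum(undef), " transcript(s) with non-positive abundance; ",
            "score set to NA", call. = FALSE)
    score[undef] <- NA_real_
  }
  setNames(as.numeric(score), names(clip_rpkm))
}

#' Aggregate replicate scores and classify targets
#'
#' @param scores matrix of replicate scores (rows = transcripts, columns =
#'   replicates, rownames = transcript ids)
#' @param stringent_min per-replicate threshold for the stringent class
#'   (default 2, met in every replicate)
#' @param high_min mean-score threshold for the high class (default 1)
#' @return data frame: `transcript_id`, `mean_clip_score`, per-replicate
#'   `clip_score_<rep>` columns, `target_class` in
#'   `{stringent, high, low, non_target}`, `has_missing`
#' @export
aggregate_and_classify <- function(scores, stringent_min = 2, high_min = 1) {
  if (is.null(dim(scores)) || nrow(scores) == 0)
    stop_contract("aggregate_and_classify: empty score input")
  has_missing <- apply(scores, 1, anyNA)
  mean_score <- rowMeans(scores)
  all_ge <- apply(scores >= stringent_min, 1, all)
  cls <- rep("non_target", nrow(scores))
  cls[!has_missing & mean_score >= 0 & mean_score < high_min] <- "low"
  cls[!has_missing & mean_score >= high_min] <- "high"
  cls[!has_missing & all_ge] <- "stringent"
  out <- data.frame(
    transcript_id = rownames(scores),
    mean_clip_score = ifelse(has_missing, NA_real_, mean_score),
    stringsAsFactors = FALSE
  )
  sc <- as.data.frame(scores)
  names(sc) <- paste0("clip_score_", colnames(scores))
  out <- cbind(out, sc)
  out$target_class <- factor(cls, levels = c("stringent", "high", "low",
                                             "non_target"))
  out$has_missing <- has_missing
  rownames(out) <- NULL
  out
}

#' Run the full CLIP-score pipeline
#'
#' Per replicate: background-subtracted CDS RPKM, abundance regression, and
#' residual scores; then aggregation and classification.
#'
#' @param counts long count table (cre_pos/cre_neg)
#' @param abundance abundance table (WT rows used)
#' @param txome transcriptome data frame
#' @param stringent_min,high_min classification thresholds
#' @param include_sentinel passed to [fit_abundance_regression()]
#' @return list: `table` (classified score table, one row per transcript),
#'   `fits` (list of `clip_fit` per replicate), `scores` (matrix), `rpkm`
#'   (matrix)
#' @export
clip_score_pipeline <- function(counts, abundance, txome,
                                stringent_min = 2, high_min = 1,
                                include_sentinel = TRUE) {
  validate_transcriptome(txome)
  pos <- count_matrix(counts, txome, "cre_pos", "cds")
  reps <- colnames(pos)
  ab <- mean_abundance(abundance, "WT")
  scores <- matrix(NA_real_, nrow(txome), length(reps),
                   dimnames = list(txome$transcript_id, reps))
  rpkm_m <- scores
  fits <- vector("list", length(reps))
  names(fits) <- reps
  for (r in reps) {
    rpkm <- compute_cds_rpkm(counts, txome, r)
    fit <- suppressWarnings(
      fit_abundance_regression(rpkm, ab, r, pos[, r],
                               include_sentinel = include_sentinel))
    scores[, r] <- suppressWarnings(compute_clip_scores(rpkm, fit, ab))
    rpkm_m[, r] <- rpkm
    fits[[r]] <- fit
  }
  tab <- aggregate_and_classify(scores, stringent_min, high_min)
  tab$gene_id <- txome$gene_id[match(tab$transcript_id, txome$transcript_id)]
  tab$had_any_tag <- rowSums(pos) > 0
  list(table = tab, fits = fits, scores = scores, rpkm = rpkm_m)
}

#' Windowed TRAP abundance (length-bias control)
#'
#' Recomputes abundance RPKM using only reads whose centers fall within a
#' window at the start or end of each transcript; the denominator length is
#' `min(window_nt, transcript length)`. Used to verify that CLIP scores are
#' not driven by transcript-length bias in the abundance estimate.
#'
#' @param trap_tags tag data frame (library `trap`)
#' @param txome transcriptome data frame
#' @param window_nt window size in nt (>= 100)
#' @param anchor `"start"` (5') or `"end"` (3')
#' @return abundance table (condition `"WT"`), `region_basis` attribute set
#'   to `window_1kb_5p`/`window_1kb_3p` style labels
#' @export
windowed_abundance <- function(trap_tags, txome, window_nt = 1000,
                               anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  if (window_nt < 100) stop_contract("window_nt must be >= 100")
  validate_transcriptome(txome)
  tags <- trap_tags[trap_tags$transcript_id %in% txome$transcript_id, ,
                    drop = FALSE]
  idx <- match(tags$transcript_id, txome$transcript_id)
  len <- txome$length[idx]
  center <- floor((tags$start + tags$end) / 2)
  w <- pmin(window_nt, len)
  in_win <- if (anchor == "start") center < w else center >= len - w
  reps <- sort(unique(tags$replicate))
  out <- vector("list", length(reps))
  eff_len <- pmin(window_nt, txome$length)
  for (i in seq_along(reps)) {
    sel <- tags$replicate == reps[i]
    total <- sum(sel)  # library size: all mapped tags of the replicate
    cnt <- table(factor(tags$transcript_id[sel & in_win],
                        levels = txome$transcript_id))
    rpkm <- as.numeric(cnt) * 1e9 / (eff_len * total)
    out[[i]] <- data.frame(
      transcript_id = txome$transcript_id, condition = "WT",
      replicate = reps[i], rpkm = rpkm,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "region_basis") <-
    if (anchor == "start") "window_5p" else "window_3p"
  res
}

#' Replicate correlation QC on CPM
#'
#' Counts per million on raw Cre-positive CDS counts (no background
#' subtraction), log2(CPM + 1) transformed, pairwise Pearson R-squared.
#'
#' @param counts long count table
#' @param txome transcriptome data frame
#' @return symmetric matrix of R-squared values with unit diagonal
#' @export
replicate_correlation <- function(counts, txome) {
  pos <- count_matrix(counts, txome, "cre_pos", "cds")
  totals <- colSums(pos)
  if (any(totals == 0)) {
    warning("replicate(s) with zero total excluded: ",
            paste(colnames(pos)[totals == 0], collapse = ", "), call. = FALSE)
    pos <- pos[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (ncol(pos) < 2) stop_contract("need >= 2 replicates with positive totals")
  cpm <- sweep(pos, 2, totals, "/") * 1e6
  r <- cor(log2(cpm + 1), method = "pearson")
  r^2
}
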