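#' KO-vs-WT regulation analysis
#'
#' Library-size normalization (median-of-ratios), a simplified paired
#' log2 fold change, class-wise CDF-shift (Kolmogorov-Smirnov) testing,
#' length/abundance-matched control sampling, and gene-set score
#' comparisons by Wilcoxon rank-sum. An externally computed fold-change
#' table (e.g. from a shrinkage-based differential-expression fit) can be
#' supplied anywhere a `lfc` vector is accepted.
#'
#' @name regulation
NULL

#' Median-of-ratios size factors
#'
#' @param count_matrix numeric matrix, rows = transcripts, columns = samples
#' @return named per-sample factor vector
#' @export
size_factors <- function(count_matrix) {
  if (ncol(count_matrix) < 2) stop_contract("size_factors: need >= 2 samples")
  log_gm <- rowMeans(log(count_matrix))
  use <- is.finite(log_gm)
  if (!any(use))
    stop_contract("size_factors: no transcript positive in all samples")
  gm <- exp(log_gm[use])
  apply(count_matrix, 2, function(cnt) median(cnt[use] / gm))
}

#' Simplified paired log2 fold change (KO vs WT)
#'
#' Per replicate pair, counts are divided by their sample size factor, a
#' pseudocount added, and the log2 ratio taken; the per-transcript LFC is
#' the mean over pairs. Columns of `ko_counts` and `wt_counts` are paired by
#' position.
#'
#' @param ko_counts,wt_counts matrices (transcripts x replicates), equal dims
#' @param factors optional list with `ko` and `wt` per-sample factor vectors;
#'   computed by [size_factors()] on the combined matrix when `NULL`
#' @param pseudocount added after normalization (default 1)
#' @return named per-transcript LFC vector
#' @export
paired_lfc <- function(ko_counts, wt_counts, factors = NULL, pseudocount = 1) {
  if (!all(dim(ko_counts) == dim(wt_counts)))
    stop_contract("paired_lfc: KO and WT matrices must have identical shape")
  k <- ncol(ko_counts)
  if (is.null(factors)) {
    f <- size_factors(cbind(ko_counts, wt_counts))
    factors <- list(ko = f[seq_len(k)], wt = f[k + seq_len(k)])
  }
  if (length(factors$ko) != k || length(factors$wt) != k)
    stop_contract("paired_lfc: factor vectors must match replicate count")
  lfc <- matrix(0, nrow(ko_counts), k)
  for (j in seq_len(k)) {
    lfc[, j] <- log2((ko_counts[, j] / factors$ko[j] + pseudocount) /
                     (wt_counts[, j] / factors$wt[j] + pseudocount))
  }
  setNames(rowMeans(lfc), rownames(ko_counts))
}

#' Class-wise CDF-shift tests on fold changes
#'
#' Two-sample two-sided Kolmogorov-Smirnov tests of each target class
#' against the non-target class and between adjacent classes. Classes with
#' fewer than `min_n` members are skipped with a warning.
#'
#' @param lfc named per-transcript log2 fold-change vector
#' @param classes factor/character of target classes aligned with `lfc`
#' @param min_n minimum class size (default 5)
#' @return list: `per_transcript` (lfc + class), `tests` (class_a, class_b,
#'   n_a, n_b, ks_d, ks_p), `medians` (per-class median lfc)
#' @export
cdf_shift_test <- function(lfc, classes, min_n = 5) {
  classes <- as.character(classes)
  keep <- !is.na(lfc) & !is.na(classes)
  lfc <- lfc[keep]; classes <- classes[keep]
  lev <- c("stringent", "high", "low", "non_target")
  present <- intersect(lev, unique(classes))
  pairs <- unique(rbind(
    do.call(rbind, lapply(setdiff(present, "non_target"),
                          function(a) c(a, "non_target"))),
    do.call(rbind, lapply(seq_len(length(present) - 1),
                          function(i) c(present[i], present[i + 1])))
  ))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- lfc[classes == pairs[i, 1]]
    b <- lfc[classes == pairs[i, 2]]
    if (length(a) < min_n || length(b) < min_n) {
      warning("class comparison ", pairs[i, 1], " vs ", pairs[i, 2],
              " skipped (below ", min_n, " members)", call. = FALSE)
      return(NULL)
    }
    kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
    data.frame(class_a = pairs[i, 1], class_b = pairs[i, 2],
               n_a = length(a), n_b = length(b),
               ks_d = unname(kt$statistic), ks_p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  meds <- tapply(lfc, factor(classes, levels = lev), median)
  list(
    per_transcript = data.frame(transcript_id = names(lfc), lfc = unname(lfc),
                                target_class = classes,
                                stringsAsFactors = FALSE),
    tests = do.call(rbind, res),
    medians = meds
  )
}

#' Sample length/abundance-matched control transcripts
#'
#' Stratified sampling: targets are binned into deciles of log10 length
#' (and, when `match_abundance`, log10 abundance; joint bins when both);
#' for each target one control is drawn without replacement from the pool's
#' same bin. When `match_abundance` is on, targets and pool are first
#' restricted to `abundance_range`. Empty bins fall back to the nearest
#' non-empty bin (logged). Deterministic under `seed`.
#'
#' @param targets,pool disjoint transcript id sets
#' @param txome transcriptome data frame (lengths)
#' @param abundance abundance table or named per-transcript RPKM vector
#'   (required when `match_abundance`)
#' @param match_length,match_abundance which variables to match on
#' @param abundance_range inclusive RPKM range filter (default c(10, 200))
#' @param seed RNG seed
#' @return list (`matched_controls`): `controls`, `targets_used`,
#'   `matching_vars`, `seed`, `n_requested`
#' @export
sample_matched_controls <- function(targets, pool, txome, abundance = NULL,
                                    match_length = TRUE,
                                    match_abundance = FALSE,
                                    abundance_range = c(10, 200), seed = 1) {
  if (length(intersect(targets, pool)))
    stop_contract("pool must be disjoint from targets")
  if (!match_length && !match_abundance)
    stop_contract("at least one matching variable must be on")
  len <- setNames(txome$length, txome$transcript_id)
  ab <- NULL
  if (match_abundance) {
    if (is.null(abundance))
      stop_contract("abundance required when match_abundance = TRUE")
    ab <- if (is.data.frame(abundance)) mean_abundance(abundance, "WT") else abundance
    in_range <- function(ids) {
      v <- ab[ids]
      ids[!is.na(v) & v >= abundance_range[1] & v <= abundance_range[2]]
    }
    n0 <- length(targets)
    targets <- in_range(targets)
    pool <- in_range(pool)
    if (length(targets) < n0)
      clip_log("sample_matched_controls: ", n0 - length(targets),
               " target(s) outside abundance range excluded")
  }
  n_req <- length(targets)
  if (!length(targets)) stop_contract("no targets left to match")

  bin_ids <- function(ids, values, breaks) {
    cut(values[ids], breaks = breaks, include.lowest = TRUE, labels = FALSE)
  }
  strata_t <- rep(1L, length(targets))
  strata_p <- rep(1L, length(pool))
  if (match_length) {
    br <- unique(quantile(log10(len[targets]), probs = seq(0, 1, 0.1)))
    if (length(br) < 2) br <- range(log10(len[targets])) + c(-1e-9, 1e-9)
    bt <- bin_ids(targets, log10(len), br)
    bp <- bin_ids(pool, log10(len), br)
    bp[is.na(bp)] <- ifelse(log10(len[pool])[is.na(bp)] < br[1], 1L,
                            length(br) - 1L)
    strata_t <- bt; strata_p <- bp
  }
  if (match_abundance) {
    br <- unique(quantile(log10(ab[targets]), probs = seq(0, 1, 0.1)))
    if (length(br) < 2) br <- range(log10(ab[targets])) + c(-1e-9, 1e-9)
    bt <- bin_ids(targets, log10(ab), br)
    bp <- bin_ids(pool, log10(ab), br)
    bp[is.na(bp)] <- ifelse(log10(ab[pool])[is.na(bp)] < br[1], 1L,
                            length(br) - 1L)
    nb <- length(br) - 1L
    strata_t <- (strata_t - 1L) * nb + bt
    strata_p <- (strata_p - 1L) * nb + bp
  }

  controls <- character(0)
  avail <- split(pool, strata_p)
  with_seed(seed, {
    for (tgt in sample(seq_along(targets))) {  # randomized target order
      b <- as.character(strata_t[tgt])
      cand_bin <- b
      if (is.null(avail[[b]]) || !length(avail[[b]])) {
        # nearest non-empty bin by index distance
        nonempty <- names(avail)[lengths(avail) > 0]
        if (!length(nonempty))
          stop_contract("matching impossible: pool exhausted")
        d <- abs(as.integer(nonempty) - as.integer(b))
        cand_bin <- nonempty[which.min(d)]
        clip_log("sample_matched_controls: empty bin ", b,
                 "; using nearest bin ", cand_bin)
      }
      pick <- sample(length(avail[[cand_bin]]), 1)
      controls <- c(controls, avail[[cand_bin]][pick])
      avail[[cand_bin]] <- avail[[cand_bin]][-pick]
    }
  })
  structure(list(
    controls = sort(controls),
    targets_used = targets,
    matching_vars = c(if (match_length) "length",
                      if (match_abundance) "abundance"),
    seed = seed,
    n_requested = n_req
  ), class = "matched_controls")
}

#' Compare a gene set's values against a background set
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test; exact enumeration when
#' the combined sample size is <= 20 and there are no ties, normal
#' approximation with tie correction otherwise. Fully tied inputs give
#' p = 1 with a warning.
#'
#' @param values named per-transcript scores or fold changes
#' @param geneset transcript id set
#' @param background transcript id set or a `matched_controls` object
#' @return list: `statistic` (W), `p`, `n_geneset`, `n_background`,
#'   `median_geneset`, `median_background`
#' @export
geneset_compare <- function(values, geneset, background) {
  if (inherits(background, "matched_controls")) background <- background$controls
  a <- values[intersect(names(values), geneset)]
  b <- values[intersect(names(values), background)]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3)
    stop_contract("geneset_compare: both groups need >= 3 members with values")
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied; p = 1", call. = FALSE)
    return(list(statistic = length(a) * length(b) / 2, p = 1,
                n_geneset = length(a), n_background = length(b),
                median_geneset = median(a), median_background = median(b)))
  }
  exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_geneset = length(a), n_background = length(b),
       median_geneset = median(a), median_background = median(b))
}

#' Object-location discrimination index
#'
#' `(time_displaced - time_unmoved) / (time_displaced + time_unmoved)`;
#' animals with total exploration below `min_total_s` are excluded (`NA`).
#' Vectorized.
#'
#' @param time_displaced,time_unmoved exploration times in seconds (>= 0)
#' @param min_total_s exclusion threshold on total exploration (default 5 s)
#' @return numeric vector in \[-1, 1\] with `NA` for excluded animals; the
#'   `excluded` attribute carries the exclusion mask
#' @export
discrimination_index <- function(time_displaced, time_unmoved,
                                 min_total_s = 5) {
  if (any(time_displaced < 0 | time_unmoved < 0, na.rm = TRUE))
    stop_contract("exploration times must be >= 0")
  total <- time_displaced + time_unmoved
  excluded <- !is.na(total) & total < min_total_s
  di <- (time_displaced - time_unmoved) / total
  di[excluded | total == 0] <- NA_real_
  attr(di, "excluded") <- excluded
  di
}

#' Read a gene set from disk
#'
#' Accepts one-id-per-line text or a two-column GMT-like TSV (set name,
#' transcript id).
#'
#' @param path file path
#' @return character vector of ids (single-column) or a named list of id
#'   vectors (two-column)
#' @export
read_geneset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(parts) == 1L)) return(unlist(parts))
  split(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
}
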