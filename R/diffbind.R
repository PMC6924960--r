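#' Cross-cell-type differential binding
#'
#' Compares per-replicate CLIP scores between two cell types for
#' transcripts with at least one Cre-positive CDS tag in every replicate of
#' both cell types, using a two-group moderated t statistic: pooled
#' per-transcript residual variances are shrunk toward a common prior
#' estimated across transcripts by method of moments on the log variance
#' scale, and the moderated t is referred to a t distribution with
#' `n_a + n_b - 2 + prior df` degrees of freedom. Calls require BH-adjusted
#' p <= `fdr_cutoff` and a mean CLIP score >= `score_min` in at least one
#' cell type.
#'
#' @name differential-binding
NULL

#' Transcripts quantifiable in both cell types
#'
#' @param counts_a,counts_b long count tables for the two cell types
#' @param txome transcriptome data frame
#' @return character vector of transcript ids with cre_pos CDS count >= 1 in
#'   every replicate of both cell types
#' @export
filter_shared_transcripts <- function(counts_a, counts_b, txome) {
  pos_a <- count_matrix(counts_a, txome, "cre_pos", "cds")
  pos_b <- count_matrix(counts_b, txome, "cre_pos", "cds")
  keep <- rowSums(pos_a >= 1) == ncol(pos_a) &
    rowSums(pos_b >= 1) == ncol(pos_b)
  txome$transcript_id[keep]
}

# invert trigamma by Newton iteration (monotone decreasing on (0, Inf))
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# method-of-moments prior (s0^2, d0) for residual variances s2 with d df,
# on the log scale: log s2 ~ log s0^2 + log F(d, d0)
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(s0_2 = mean(s2[ok]), d0 = 0))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- var(z) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0) {
    # variances more concentrated than chi-square scatter: infinite prior df
    return(list(s0_2 = exp(mean(e)), d0 = Inf))
  }
  half_d0 <- trigamma_inverse(ev)
  d0 <- 2 * half_d0
  s0_2 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  list(s0_2 = s0_2, d0 = d0)
}

#' Moderated two-group comparison of replicate CLIP scores
#'
#' @param scores_a,scores_b matrices (transcripts x replicates, >= 2 columns
#'   each) with identical rownames
#' @param fdr_cutoff adjusted-p threshold for calls (default 0.05)
#' @param score_min minimum mean score in at least one cell type for a call
#'   (default 0)
#' @param prior_df override the estimated prior degrees of freedom (mainly
#'   for testing; `0` gives the ordinary pooled t)
#' @return data frame: `transcript_id`, `mean_score_a`, `mean_score_b`,
#'   `delta`, `t_moderated`, `df_total`, `p`, `adj_p`, `call` in
#'   `{enriched_a, enriched_b, ns}`; attributes `prior_df`, `prior_var`
#' @export
moderated_compare <- function(scores_a, scores_b, fdr_cutoff = 0.05,
                              score_min = 0, prior_df = NULL) {
  if (ncol(scores_a) < 2 || ncol(scores_b) < 2)
    stop_contract("moderated_compare: need >= 2 replicates per cell type")
  if (!identical(rownames(scores_a), rownames(scores_b)))
    stop_contract("moderated_compare: row names must match")
  na <- ncol(scores_a); nb <- ncol(scores_b)
  d <- na + nb - 2
  mean_a <- rowMeans(scores_a); mean_b <- rowMeans(scores_b)
  ss <- rowSums((scores_a - mean_a)^2) + rowSums((scores_b - mean_b)^2)
  s2 <- ss / d
  if (all(s2 == 0 | !is.finite(s2))) {
    warning("zero residual variance everywhere; using ordinary t with ",
            "pooled variance", call. = FALSE)
    prior <- list(s0_2 = 0, d0 = 0)
  } else if (!is.null(prior_df)) {
    prior <- list(s0_2 = mean(s2[is.finite(s2) & s2 > 0]), d0 = prior_df)
  } else {
    prior <- fit_variance_prior(s2, d)
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  delta <- mean_a - mean_b
  t_mod <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  df_total <- d + d0
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p[t_mod == 0] <- 1
  adj <- bh_fdr(p)
  call <- rep("ns", length(p))
  eligible <- !is.na(adj) & adj <= fdr_cutoff & pmax(mean_a, mean_b) >= score_min
  call[eligible & delta > 0] <- "enriched_a"
  call[eligible & delta < 0] <- "enriched_b"
  out <- data.frame(
    transcript_id = rownames(scores_a),
    mean_score_a = mean_a, mean_score_b = mean_b,
    delta = delta, t_moderated = t_mod, df_total = df_total,
    p = p, adj_p = adj,
    call = factor(call, levels = c("enriched_a", "enriched_b", "ns")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s0_2
  out
}

#' Full differential-binding pipeline for two cell types
#'
#' Runs [clip_score_pipeline()] in each cell type, restricts to
#' [filter_shared_transcripts()], and compares replicate scores with
#' [moderated_compare()].
#'
#' @param counts_a,counts_b long CLIP count tables
#' @param abundance_a,abundance_b abundance tables (WT rows used)
#' @param txome transcriptome data frame
#' @param ... passed to [moderated_compare()]
#' @return list: `table` (the `moderated_compare` result), `shared_ids`,
#'   `pipeline_a`, `pipeline_b`
#' @export
diffbind_pipeline <- function(counts_a, counts_b, abundance_a, abundance_b,
                              txome, ...) {
  shared <- filter_shared_transcripts(counts_a, counts_b, txome)
  if (!length(shared))
    stop_contract("no transcripts with tags in every replicate of both cell types")
  pa <- clip_score_pipeline(counts_a, abundance_a, txome)
  pb <- clip_score_pipeline(counts_b, abundance_b, txome)
  sa <- pa$scores[shared, , drop = FALSE]
  sb <- pb$scores[shared, , drop = FALSE]
  ok <- !apply(sa, 1, anyNA) & !apply(sb, 1, anyNA)
  tab <- moderated_compare(sa[ok, , drop = FALSE], sb[ok, , drop = FALSE], ...)
  list(table = tab, shared_ids = shared, pipeline_a = pa, pipeline_b = pb)
}
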