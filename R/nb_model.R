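#' Count-based negative-binomial significance variant
#'
#' Instead of RPKM residuals, this variant models background-subtracted CLIP
#' CDS counts as negative binomial with mean \eqn{\mu} (from a per-replicate
#' log-log regression of CLIP on TRAP CDS counts) and dispersion
#' \eqn{\alpha} (variance \eqn{\mu + \alpha \mu^2}, estimated from replicate
#' variability with a parametric mean-dispersion trend). A one-sided
#' p-value \eqn{P(X \ge x_{obs})} is computed per replicate, combined with
#' Fisher's method, and converted to FDR by Benjamini-Hochberg.
#'
#' @name nb-model
NULL

#' Estimate the dispersion trend from replicate variability
#'
#' Per-transcript method-of-moments dispersion
#' \eqn{\hat\alpha_i = \max(0, (s_i^2 - m_i)/m_i^2)} from the replicate mean
#' and variance, followed by a parametric trend
#' \eqn{\alpha(\mu) = a_0/\mu + a_1} fitted by iteratively reweighted least
#' squares over transcripts with positive raw dispersion. The dispersion used
#' for a transcript is the trend value at its mean (no per-gene shrinkage).
#'
#' @param clip_counts numeric matrix of (background-subtracted, floored at 0)
#'   CLIP CDS counts, rows = transcripts, columns = replicates (>= 2)
#' @return a `dispersion_model` list: `a0`, `a1`, `raw` (per-transcript
#'   estimates), `dispersion_at(mu)` function, `n_used`, `fallback` flag
#' @export
estimate_dispersion <- function(clip_counts) {
  if (is.null(dim(clip_counts)) || ncol(clip_counts) < 2)
    stop_contract("estimate_dispersion: need >= 2 replicates")
  m <- rowMeans(clip_counts)
  if (sum(m > 0) < 50)
    stop_contract("estimate_dispersion: need >= 50 transcripts with positive mean")
  s2 <- row_vars(clip_counts)
  raw <- pmax(0, (s2 - m) / m^2)
  raw[m <= 0] <- NA_real_
  use <- which(!is.na(raw) & raw > 0 & m > 0)
  fallback <- FALSE
  a0 <- 0; a1 <- median(raw[use], na.rm = TRUE)
  if (length(use) >= 10) {
    fit <- tryCatch({
      x <- 1 / m[use]; y <- raw[use]
      co <- coef(lm(y ~ x))  # init
      for (it in 1:8) {
        pred <- pmax(co[1] + co[2] * x, 1e-8)
        w <- 1 / pred^2  # gamma-like variance weighting
        co <- coef(lm(y ~ x, weights = w))
      }
      c(a0 = max(0, unname(co[2])), a1 = max(0, unname(co[1])))
    }, error = function(e) NULL)
    if (is.null(fit)) {
      warning("dispersion trend fit failed; falling back to median raw ",
              "dispersion", call. = FALSE)
      fallback <- TRUE
    } else {
      a0 <- fit[["a0"]]; a1 <- fit[["a1"]]
    }
  } else {
    warning("too few positive raw dispersions for a trend; using median",
            call. = FALSE)
    fallback <- TRUE
  }
  if (fallback && (!is.finite(a1) || a1 < 0)) a1 <- 0
  structure(list(
    a0 = a0, a1 = a1, raw = raw, n_used = length(use), fallback = fallback,
    dispersion_at = function(mu) pmax(0, a0 / mu + a1)
  ), class = "dispersion_model")
}

#' Per-replicate expected CLIP counts from the log-log count regression
#'
#' OLS of log(subtracted CLIP count) on log(TRAP count) over transcripts
#' with positive subtracted CLIP count and positive TRAP count; every
#' transcript with a positive TRAP count receives an expected count
#' `mu = exp(fitted)`.
#'
#' @param clip_cds_counts numeric vector of background-subtracted CLIP CDS
#'   counts (may contain non-positive values; excluded from the fit only)
#' @param trap_cds_counts numeric vector of TRAP CDS counts
#' @param replicate replicate identifier (metadata)
#' @return list: `mu` (named vector, `NA` where TRAP count <= 0), `slope`,
#'   `intercept`, `n_fit`, `replicate_id`
#' @export
fit_count_regression <- function(clip_cds_counts, trap_cds_counts, replicate) {
  if (length(clip_cds_counts) != length(trap_cds_counts))
    stop_contract("count vectors must have equal length")
  elig <- clip_cds_counts > 0 & trap_cds_counts > 0 &
    !is.na(clip_cds_counts) & !is.na(trap_cds_counts)
  if (sum(elig) < 3)
    stop_contract("fit_count_regression: fewer than 3 eligible transcripts")
  x <- log(trap_cds_counts[elig])
  y <- log(clip_cds_counts[elig])
  if (sd(x) == 0) stop_contract("fit_count_regression: degenerate fit (constant x)")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  mu <- rep(NA_real_, length(trap_cds_counts))
  ok <- trap_cds_counts > 0 & !is.na(trap_cds_counts)
  mu[ok] <- exp(intercept + slope * log(trap_cds_counts[ok]))
  names(mu) <- names(clip_cds_counts)
  list(mu = mu, slope = slope, intercept = intercept, n_fit = sum(elig),
       replicate_id = replicate)
}

#' One-sided negative-binomial tail p-value
#'
#' \eqn{p = P(X \ge x_{obs})} under NB with mean `mu` and dispersion `alpha`
#' (variance \eqn{\mu + \alpha\mu^2}); the Poisson limit is used at
#' `alpha = 0`. The tail includes the observed value, so `p(0) = 1` exactly.
#' Vectorized over all arguments.
#'
#' @param observed non-negative integer count(s)
#' @param mu expected count(s), > 0
#' @param alpha dispersion(s), >= 0
#' @return p-value(s) in \[0, 1\]
#' @export
nb_pvalue <- function(observed, mu, alpha) {
  n <- max(length(observed), length(mu), length(alpha))
  observed <- rep_len(observed, n); mu <- rep_len(mu, n)
  alpha <- rep_len(alpha, n)
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop_contract("nb_pvalue: mu must be finite and > 0")
  if (any(observed < 0)) stop_contract("nb_pvalue: observed must be >= 0")
  if (any(alpha < 0)) stop_contract("nb_pvalue: alpha must be >= 0")
  p <- numeric(n)
  pois <- alpha == 0
  if (any(pois))
    p[pois] <- ppois(observed[pois] - 1, mu[pois], lower.tail = FALSE)
  if (any(!pois))
    p[!pois] <- pnbinom(observed[!pois] - 1, mu = mu[!pois],
                        size = 1 / alpha[!pois], lower.tail = FALSE)
  pmin(1, pmax(0, p))
}

#' Combine replicate p-values with Fisher's method
#'
#' \eqn{\chi^2 = -2\sum_j \ln p_j}, compared to a chi-square distribution
#' with 2k degrees of freedom. Zero p-values are clipped to the smallest
#' positive double (never dropped).
#'
#' @param p_values vector of k p-values in (0, 1\]
#' @return list: `chi2`, `p_combined`, `df`
#' @export
combine_fisher <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop_contract("combine_fisher: empty input")
  if (any(p < 0 | p > 1)) stop_contract("combine_fisher: p-values outside [0,1]")
  if (any(p == 0)) {
    clip_log("combine_fisher: clipped ", sum(p == 0), " zero p-value(s)")
    p[p == 0] <- .Machine$double.xmin
  }
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chi2 = chi2, p_combined = pchisq(chi2, df, lower.tail = FALSE), df = df)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up adjustment mapped back to input order; `NA` p-values
#' yield `NA` q-values.
#'
#' @param p_values vector of p-values in \[0, 1\]
#' @return vector of q-values
#' @export
bh_fdr <- function(p_values) {
  p.adjust(p_values, method = "BH")
}

#' Run the count-based NB significance pipeline
#'
#' Background-subtracts Cre-negative from Cre-positive CDS counts, fits the
#' per-replicate log-log count regression against TRAP CDS counts, estimates
#' the dispersion trend from the subtracted count matrix, computes one-sided
#' NB p-values per replicate (observed = subtracted count floored at 0),
#' combines them with Fisher's method and applies BH FDR. Count-scale CLIP
#' scores are the mean log2 residual over replicates with positive
#' subtracted counts.
#'
#' @param counts long CLIP count table (cre_pos/cre_neg)
#' @param abundance abundance table carrying TRAP `cds_count` (WT rows), or
#'   a named per-transcript TRAP count vector
#' @param txome transcriptome data frame
#' @return list: `table` (per-transcript results: mu/p per replicate,
#'   `clip_score_counts`, `fisher_chi2`, `p_combined`, `fdr`), `dispersion`
#'   (the `dispersion_model`), `fits` (per-replicate regression metadata)
#' @export
nb_test_pipeline <- function(counts, abundance, txome) {
  validate_transcriptome(txome)
  pos <- count_matrix(counts, txome, "cre_pos", "cds")
  neg <- count_matrix(counts, txome, "cre_neg", "cds")
  reps <- colnames(pos)
  sub <- pos - neg[, reps, drop = FALSE]
  if (is.data.frame(abundance)) {
    ab <- abundance
    if ("condition" %in% names(ab)) ab <- ab[ab$condition == "WT", , drop = FALSE]
    trap <- tapply(ab$cds_count, ab$transcript_id, mean)
    trap <- as.numeric(trap[txome$transcript_id])
  } else {
    trap <- as.numeric(abundance[txome$transcript_id])
  }
  # analysis set: at least one positive subtracted CLIP count across replicates
  in_set <- rowSums(pmax(sub, 0)) >= 1
  disp <- estimate_dispersion(pmax(sub, 0))
  mu_m <- matrix(NA_real_, nrow(txome), length(reps),
                 dimnames = list(txome$transcript_id, reps))
  p_m <- mu_m
  resid_m <- mu_m
  fits <- vector("list", length(reps)); names(fits) <- reps
  for (r in reps) {
    fit <- fit_count_regression(sub[, r], trap, r)
    fits[[r]] <- fit[c("slope", "intercept", "n_fit", "replicate_id")]
    mu_m[, r] <- fit$mu
    ok <- !is.na(fit$mu)
    alpha_r <- disp$dispersion_at(fit$mu[ok])
    p_m[ok, r] <- nb_pvalue(pmax(sub[ok, r], 0), fit$mu[ok], alpha_r)
    pos_sub <- ok & sub[, r] > 0
    resid_m[pos_sub, r] <- log2(sub[pos_sub, r]) - log2(mu_m[pos_sub, r])
  }
  comb <- apply(p_m, 1, function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(c(NA_real_, NA_real_))
    f <- combine_fisher(p)
    c(f$chi2, f$p_combined)
  })
  tab <- data.frame(transcript_id = txome$transcript_id,
                    stringsAsFactors = FALSE)
  for (r in reps) tab[[paste0("mu_", r)]] <- mu_m[, r]
  for (r in reps) tab[[paste0("p_", r)]] <- p_m[, r]
  tab$clip_score_counts <- rowMeans(resid_m, na.rm = TRUE)
  tab$clip_score_counts[!is.finite(tab$clip_score_counts)] <- NA_real_
  tab$fisher_chi2 <- comb[1, ]
  tab$p_combined <- comb[2, ]
  tab$in_analysis_set <- in_set
  tab$fdr <- NA_real_
  tab$fdr[in_set] <- bh_fdr(tab$p_combined[in_set])
  list(table = tab, dispersion = disp, fits = fits)
}
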