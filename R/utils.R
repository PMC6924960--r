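#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef median quantile var sd pchisq ppois pnbinom
#'   p.adjust ks.test wilcox.test rnorm rlnorm rpois rnbinom runif pt
#'   setNames digamma trigamma psigamma punif cor
#' @importFrom utils read.delim write.table head modifyList
NULL

clip_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

stop_contract <- function(...) {
  stop(..., call. = FALSE)
}

#' Write a table as TSV atomically
#'
#' Writes to a temporary file in the destination directory and renames it into
#' place so partially written outputs are never observed. Missing values are
#' encoded as `"."`.
#'
#' @param x data frame to write
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_tsv_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  file.rename(tmp, path)
  invisible(path)
}

#' Read a TSV table written by this package
#'
#' @param path file path
#' @return data frame, with `"."` decoded to `NA`
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
             stringsAsFactors = FALSE, check.names = FALSE)
}

# row-wise sample variance of a numeric matrix (denominator n - 1)
row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' @param score numeric predictor
#' @param label logical (or 0/1) ground truth; `TRUE` is the positive class
#' @return AUC in \[0, 1\]; ties share rank mass
#' @export
rank_auc <- function(score, label) {
  label <- as.logical(label)
  keep <- is.finite(score) & !is.na(label)
  score <- score[keep]; label <- label[keep]
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L)
    stop_contract("rank_auc: both classes must be non-empty")
  r <- rank(score)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# run `expr` under a private RNG stream seeded with `seed`; global RNG state
# is untouched
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# derive a stable sub-seed for a named stage from the run seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}
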