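#' Read-distribution summaries
#'
#' Feature-level genic distribution, per-transcript nucleotide coverage and
#' the weighted meta-transcript ("metagene") profile around start/stop
#' codons.
#'
#' @name coverage-profile
NULL

tag_center <- function(tags) floor((tags$start + tags$end) / 2)

#' Genic distribution of reads across feature classes
#'
#' Each read is assigned to exactly one feature class (5'UTR, CDS, 3'UTR,
#' intron, intergenic) by the position of its center. Transcript-space
#' annotation carries no introns, so the intron class is structurally empty;
#' reads on transcripts absent from the annotation are intergenic. The
#' length-normalized density divides each class count by the total length of
#' that class across the annotation (undefined, `NA`, for intergenic).
#'
#' @param tags tag data frame
#' @param txome transcriptome data frame
#' @return data frame: `feature`, `count`, `raw_fraction`, `total_length`,
#'   `length_normalized_density`
#' @export
genic_distribution <- function(tags, txome) {
  validate_transcriptome(txome)
  idx <- match(tags$transcript_id, txome$transcript_id)
  center <- tag_center(tags)
  feature <- rep("intergenic", nrow(tags))
  known <- !is.na(idx)
  inside <- known & center >= 0 & center < txome$length[ifelse(known, idx, 1)]
  feature[inside & center < txome$cds_start[idx]] <- "utr5"
  feature[inside & center >= txome$cds_start[idx] &
            center < txome$cds_end[idx]] <- "cds"
  feature[inside & center >= txome$cds_end[idx]] <- "utr3"
  classes <- c("utr5", "cds", "utr3", "intron", "intergenic")
  cnt <- as.numeric(table(factor(feature, levels = classes)))
  total_len <- c(
    utr5 = sum(txome$cds_start),
    cds = sum(txome$cds_length),
    utr3 = sum(txome$length - txome$cds_end),
    intron = 0,
    intergenic = NA_real_
  )
  data.frame(
    feature = classes,
    count = cnt,
    raw_fraction = cnt / sum(cnt),
    total_length = as.numeric(total_len),
    length_normalized_density = ifelse(total_len > 0, cnt / total_len, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Per-nucleotide coverage of one transcript
#'
#' @param tags tag data frame (only rows on `transcript_id` are used)
#' @param transcript a single row of a transcriptome data frame, or a
#'   transcript id looked up in `txome`
#' @param txome transcriptome data frame (needed when `transcript` is an id)
#' @return integer vector of length `transcript length`; `coverage[n]` is
#'   the number of tag intervals containing position `n - 1` (0-based)
#' @export
transcript_coverage <- function(tags, transcript, txome = NULL) {
  if (is.character(transcript)) {
    if (is.null(txome)) stop_contract("txome required when transcript is an id")
    transcript <- txome[txome$transcript_id == transcript, , drop = FALSE]
    if (!nrow(transcript)) stop_contract("unknown transcript")
  }
  len <- transcript$length[1]
  t_tags <- tags[tags$transcript_id == transcript$transcript_id[1], ,
                 drop = FALSE]
  if (!nrow(t_tags)) return(integer(len))
  # 0-based half-open [start, end) -> 1-based inclusive IRanges
  ir <- IRanges::IRanges(start = t_tags$start + 1L, end = t_tags$end)
  cov <- IRanges::coverage(ir, width = len)
  as.integer(cov)
}

#' Weighted meta-transcript coverage profile
#'
#' Implements the equal-representation metagene procedure: (1) transcripts
#' are ranked by whole-transcript tag density (tags/length) and the `top_n`
#' densest are selected; (2) reads are assigned a signed offset of their
#' center from the anchor (first nucleotide of the start codon, or first
#' nucleotide of the stop codon, i.e. `cds_end - 3`) and kept when the
#' offset lies in `[-flank_nt, flank_nt)` and the center is inside the
#' transcript; (3) each kept read is weighted by 1/R_t, where R_t is the
#' number of kept reads of its transcript, so every contributing transcript
#' carries total weight 1; (4) weighted contributions are binned into
#' `bin_nt` windows; (5) each bin is divided by the fraction of the `top_n`
#' transcripts whose structure fully covers that window.
#'
#' @param tags tag data frame
#' @param txome transcriptome data frame
#' @param top_n number of densest transcripts to use (default 1000)
#' @param bin_nt bin width in nt (default 10); `flank_nt` must be a multiple
#' @param anchor `"start_codon"` or `"stop_codon"`
#' @param flank_nt half-width of the profiled region in nt
#' @return data frame: `offset_bin_start`, `weighted_coverage`,
#'   `representation`, `normalized_coverage` (`NA` where representation is
#'   zero); attribute `transcripts` lists the selected ids
#' @export
metagene_profile <- function(tags, txome, top_n = 1000, bin_nt = 10,
                             anchor = c("start_codon", "stop_codon"),
                             flank_nt = 1000) {
  anchor <- match.arg(anchor)
  validate_transcriptome(txome)
  if (flank_nt %% bin_nt != 0)
    stop_contract("flank_nt must be a multiple of bin_nt")
  n_tags <- table(factor(tags$transcript_id, levels = txome$transcript_id))
  with_tag <- sum(n_tags > 0)
  if (top_n > with_tag)
    stop_contract("top_n (", top_n, ") exceeds transcripts with tags (",
                  with_tag, ")")
  density <- as.numeric(n_tags) / txome$length
  ord <- order(-density, txome$transcript_id)
  sel <- txome[ord[seq_len(top_n)], , drop = FALSE]

  anchor_pos <- if (anchor == "start_codon") sel$cds_start else sel$cds_end - 3L
  names(anchor_pos) <- sel$transcript_id

  t_tags <- tags[tags$transcript_id %in% sel$transcript_id, , drop = FALSE]
  idx <- match(t_tags$transcript_id, sel$transcript_id)
  center <- tag_center(t_tags)
  offset <- center - anchor_pos[idx]
  keep <- offset >= -flank_nt & offset < flank_nt &
    center >= 0 & center < sel$length[idx]
  t_tags <- t_tags[keep, , drop = FALSE]
  offset <- offset[keep]
  idx <- idx[keep]

  r_t <- table(factor(t_tags$transcript_id, levels = sel$transcript_id))
  wt <- 1 / as.numeric(r_t)[idx]

  bin_starts <- seq(-flank_nt, flank_nt - bin_nt, by = bin_nt)
  bin_of <- floor(offset / bin_nt) * bin_nt
  weighted <- tapply(wt, factor(bin_of, levels = bin_starts), sum)
  weighted[is.na(weighted)] <- 0

  # structural representation: transcript long enough that the whole bin
  # [anchor + b, anchor + b + bin_nt) lies inside it
  rep_frac <- vapply(bin_starts, function(b) {
    lo <- anchor_pos + b
    mean(lo >= 0 & lo + bin_nt <= sel$length)
  }, numeric(1))

  out <- data.frame(
    offset_bin_start = bin_starts,
    weighted_coverage = as.numeric(weighted),
    representation = rep_frac,
    normalized_coverage = ifelse(rep_frac > 0,
                                 as.numeric(weighted) / rep_frac, NA_real_)
  )
  attr(out, "transcripts") <- sel$transcript_id
  out
}
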