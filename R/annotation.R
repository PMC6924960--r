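#' Transcript annotation, tag ingestion and count tables
#'
#' The package works in transcript space throughout: every interval is a
#' 0-based half-open `[start, end)` range on a transcript, and every gene is
#' represented by a single principal transcript after
#' [select_principal_transcripts()]. A transcriptome is a data frame with
#' columns `transcript_id`, `gene_id`, `length`, `cds_start`, `cds_end`,
#' `cds_length`.
#'
#' @name annotation
NULL

validate_transcriptome <- function(txome) {
  req <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end",
           "cds_length")
  missing <- setdiff(req, names(txome))
  if (length(missing))
    stop_contract("transcriptome missing columns: ",
                  paste(missing, collapse = ", "))
  if (anyDuplicated(txome$transcript_id))
    stop_contract("transcript_id values must be unique")
  bad <- txome$cds_start < 0 | txome$cds_start >= txome$cds_end |
    txome$cds_end > txome$length
  if (any(bad))
    stop_contract("CDS outside transcript bounds for: ",
                  paste(head(txome$transcript_id[bad], 5), collapse = ", "))
  if (any(txome$cds_length != txome$cds_end - txome$cds_start))
    stop_contract("cds_length inconsistent with cds_start/cds_end")
  invisible(txome)
}

#' Read transcript annotation (BED12 or transcript-space GTF)
#'
#' BED12: the `chrom` field holds the transcript identifier, the `name` field
#' the gene identifier, and `thickStart`/`thickEnd` delimit the CDS (BED
#' 0-based half-open coordinates are the package's native convention).
#' GTF: transcript-space records (seqname = transcript identifier) with
#' `exon`/`transcript` features giving the transcript extent and `CDS`
#' features giving the coding region; `gene_id` and `transcript_id`
#' attributes are required, and 1-based inclusive GTF coordinates are
#' converted on read. Transcripts without a CDS are dropped with a logged
#' count.
#'
#' @param path file path
#' @param format `"bed12"` or `"gtf"`
#' @return a transcriptome data frame (see [annotation])
#' @export
read_annotation <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_contract("annotation file not found: ", path)
  if (format == "bed12") {
    nfield <- lengths(strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE))
    bad <- which(nfield > 0 & nfield < 12)
    if (length(bad))
      stop_contract("malformed BED12 record at line ", bad[1],
                    " of ", path, " (", nfield[bad[1]], " fields)")
    gr <- rtracklayer::import(path, format = "bed")
    thick <- gr$thick
    df <- data.frame(
      transcript_id = as.character(GenomicRanges::seqnames(gr)),
      gene_id = as.character(gr$name),
      length = BiocGenerics::width(gr),
      cds_start = BiocGenerics::start(thick) - 1L,
      cds_end = BiocGenerics::end(thick),
      stringsAsFactors = FALSE
    )
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    type <- as.character(gr$type)
    if (is.null(gr$transcript_id) || is.null(gr$gene_id))
      stop_contract("GTF must carry gene_id and transcript_id attributes")
    span <- gr[type %in% c("exon", "transcript")]
    cds <- gr[type == "CDS"]
    if (!length(span)) stop_contract("GTF contains no exon/transcript features")
    len <- tapply(BiocGenerics::end(span), span$transcript_id, max)
    gene <- tapply(as.character(span$gene_id), span$transcript_id,
                   function(g) g[1])
    cds_s <- tapply(BiocGenerics::start(cds), cds$transcript_id, min)
    cds_e <- tapply(BiocGenerics::end(cds), cds$transcript_id, max)
    ids <- names(len)
    df <- data.frame(
      transcript_id = ids,
      gene_id = as.character(gene[ids]),
      length = as.integer(len[ids]),
      cds_start = as.integer(cds_s[ids]) - 1L,  # GTF 1-based -> 0-based
      cds_end = as.integer(cds_e[ids]),
      stringsAsFactors = FALSE
    )
    df$cds_start[is.na(df$cds_start)] <- NA_integer_
  }
  no_cds <- is.na(df$cds_start) | is.na(df$cds_end) |
    df$cds_end <= df$cds_start
  if (any(no_cds)) {
    clip_log("read_annotation: dropped ", sum(no_cds),
             " transcript(s) without a CDS")
    df <- df[!no_cds, , drop = FALSE]
  }
  df$cds_length <- df$cds_end - df$cds_start
  df <- df[order(df$transcript_id), , drop = FALSE]
  rownames(df) <- NULL
  validate_transcriptome(df)
  df
}

#' Write a transcriptome as BED12
#'
#' Inverse of [read_annotation()] for the BED12 convention used by the
#' package (chrom = transcript_id, name = gene_id, thick = CDS).
#'
#' @param txome transcriptome data frame
#' @param path destination
#' @return `path`, invisibly
#' @export
write_annotation_bed12 <- function(txome, path) {
  validate_transcriptome(txome)
  bed <- data.frame(
    chrom = txome$transcript_id,
    chromStart = 0L,
    chromEnd = txome$length,
    name = txome$gene_id,
    score = 0L,
    strand = "+",
    thickStart = txome$cds_start,
    thickEnd = txome$cds_end,
    itemRgb = "0,0,0",
    blockCount = 1L,
    blockSizes = paste0(txome$length, ","),
    blockStarts = "0,"
  )
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.table(bed, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Keep one transcript per gene and apply the expression filter
#'
#' For each gene, retains the transcript with the highest mean wild-type
#' RPKM; ties are broken by the lexicographically smaller `transcript_id`.
#' Genes whose best transcript falls below `min_rpkm` mean RPKM are removed.
#' The operation is idempotent.
#'
#' @param txome transcriptome data frame
#' @param abundance abundance table (long data frame with `transcript_id`,
#'   `condition`, `replicate`, `rpkm`); mean RPKM is taken over `"WT"` rows
#'   when a condition column is present, otherwise over all rows
#' @param min_rpkm minimum mean RPKM to retain a gene (default 1)
#' @return filtered transcriptome with one transcript per gene
#' @export
select_principal_transcripts <- function(txome, abundance, min_rpkm = 1) {
  validate_transcriptome(txome)
  ab <- abundance
  if ("condition" %in% names(ab) && any(ab$condition == "WT"))
    ab <- ab[ab$condition == "WT", , drop = FALSE]
  mean_rpkm <- tapply(ab$rpkm, ab$transcript_id, mean)
  txome$mean_rpkm <- as.numeric(mean_rpkm[txome$transcript_id])
  txome <- txome[!is.na(txome$mean_rpkm), , drop = FALSE]
  # highest mean RPKM per gene; lexicographic transcript_id breaks ties
  txome <- txome[order(txome$gene_id, -txome$mean_rpkm, txome$transcript_id), ,
                 drop = FALSE]
  keep <- !duplicated(txome$gene_id)
  out <- txome[keep & txome$mean_rpkm >= min_rpkm, , drop = FALSE]
  out$mean_rpkm <- NULL
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read tag positions from 6-column BED
#'
#' Transcript-space tags: `chrom` is the transcript identifier and the `name`
#' field encodes `replicate|library` with library one of `cre_pos`,
#' `cre_neg`, `trap`.
#'
#' @param path BED file path
#' @return data frame with columns `transcript_id`, `start`, `end`,
#'   `replicate`, `library`
#' @export
read_tags_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- strsplit(as.character(gr$name), "|", fixed = TRUE)
  lib <- vapply(nm, function(x) if (length(x) >= 2) x[2] else NA_character_, "")
  bad_lib <- !lib %in% c("cre_pos", "cre_neg", "trap")
  if (any(bad_lib))
    stop_contract("tag BED name field must be 'replicate|library' with ",
                  "library in {cre_pos, cre_neg, trap}")
  data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    replicate = vapply(nm, `[`, "", 1L),
    library = lib,
    stringsAsFactors = FALSE
  )
}

#' Write tag positions as 6-column BED
#'
#' @param tags tag data frame (`transcript_id`, `start`, `end`, `replicate`,
#'   `library`)
#' @param path destination
#' @return `path`, invisibly
#' @export
write_tags_bed <- function(tags, path) {
  bed <- data.frame(
    chrom = tags$transcript_id,
    start = tags$start,
    end = tags$end,
    name = paste(tags$replicate, tags$library, sep = "|"),
    score = 0L,
    strand = "+"
  )
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.table(bed, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Count tags per transcript
#'
#' A tag is counted towards a transcript's CDS when its interval overlaps
#' `[cds_start, cds_end)` by at least one nucleotide; `full_count` counts all
#' tags on the transcript. Tags referencing unknown transcripts are skipped
#' with a warning carrying the skipped count.
#'
#' @param tags tag data frame (see [read_tags_bed()])
#' @param txome transcriptome data frame
#' @return a count table: one row per (transcript, replicate, library) with
#'   `cds_count` and `full_count`
#' @export
counts_from_tags <- function(tags, txome) {
  validate_transcriptome(txome)
  known <- tags$transcript_id %in% txome$transcript_id
  if (!all(known)) {
    warning(sum(!known), " tag(s) reference unknown transcripts; skipped",
            call. = FALSE)
    tags <- tags[known, , drop = FALSE]
  }
  if (any(tags$start < 0 | tags$start >= tags$end))
    stop_contract("tag intervals must satisfy 0 <= start < end")
  idx <- match(tags$transcript_id, txome$transcript_id)
  if (any(tags$end > txome$length[idx]))
    stop_contract("tag interval extends beyond transcript length")
  in_cds <- tags$start < txome$cds_end[idx] & tags$end > txome$cds_start[idx]
  key <- paste(tags$transcript_id, tags$replicate, tags$library, sep = "\r")
  full <- tapply(rep(1L, nrow(tags)), key, sum)
  cds <- tapply(as.integer(in_cds), key, sum)
  parts <- strsplit(names(full), "\r", fixed = TRUE)
  out <- data.frame(
    transcript_id = vapply(parts, `[`, "", 1L),
    replicate = vapply(parts, `[`, "", 2L),
    library = vapply(parts, `[`, "", 3L),
    cds_count = as.integer(cds),
    full_count = as.integer(full),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$transcript_id, out$replicate, out$library), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reshape a long count table into a transcripts x replicates matrix
#'
#' Transcripts absent from the table get zero counts.
#'
#' @param counts long count table (`transcript_id`, `replicate`, `library`,
#'   `cds_count`, `full_count`)
#' @param txome transcriptome data frame fixing row order
#' @param library which library to extract
#' @param region `"cds"` or `"full"` counts
#' @return integer matrix, rows = transcripts, columns = replicates
#' @export
count_matrix <- function(counts, txome, library = c("cre_pos", "cre_neg", "trap"),
                         region = c("cds", "full")) {
  library <- match.arg(library)
  region <- match.arg(region)
  cc <- counts[counts$library == library, , drop = FALSE]
  reps <- sort(unique(cc$replicate))
  m <- matrix(0L, nrow = nrow(txome), ncol = length(reps),
              dimnames = list(txome$transcript_id, reps))
  col <- if (region == "cds") cc$cds_count else cc$full_count
  ridx <- match(cc$transcript_id, txome$transcript_id)
  keep <- !is.na(ridx)
  m[cbind(ridx[keep], match(cc$replicate[keep], reps))] <- col[keep]
  m
}
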