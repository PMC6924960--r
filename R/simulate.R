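#' Synthetic CLIP/TRAP experiment generator
#'
#' Generates a transcriptome, replicated TRAP abundances (WT and KO),
#' replicated CLIP coding-region counts (Cre-positive signal and Cre-negative
#' background), and a ground-truth table, under a fully specified generative
#' model:
#'
#' * transcript lengths are log-normal; the CDS occupies a Beta-distributed
#'   fraction of the transcript centred on `cds_fraction_mean`;
#' * underlying abundance \eqn{A_i} (RPKM scale) is log-normal;
#' * a fraction `target_fraction` of transcripts are true targets with
#'   binding enrichment \eqn{2^{b_i}}, \eqn{b_i \sim N(\mu_b, \sigma_b)}
#'   in log2 units; non-targets have \eqn{b_i = 0};
#' * CLIP CDS counts are negative binomial with mean
#'   \eqn{s_j \, c \, A_i^{\beta} \, 2^{b_i} \, L^{CDS}_i/10^3} and dispersion
#'   `dispersion_alpha`, where the replicate size factor \eqn{s_j} is
#'   log-normal around 1 and \eqn{c} scales expected totals to `depth_clip`;
#' * Cre-negative background counts are negative binomial with mean equal to
#'   `background_fraction` times the same quantity without the binding
#'   factor (nonspecific capture is binding-independent);
#' * TRAP CDS counts are negative binomial around
#'   \eqn{A_i L^{CDS}_i/10^3} scaled to `depth_trap`, with dispersion
#'   `trap_dispersion`; KO abundance is WT abundance times
#'   \eqn{2^{\mathrm{lfc}_i}} with
#'   \eqn{\mathrm{lfc}_i = -\gamma b_i + N(0, \sigma_{ko})}.
#'
#' All sampling is driven by stage-specific streams derived from the single
#' run seed, so a fixed seed gives byte-identical outputs.
#'
#' @name synthetic-data
NULL

#' Build a simulation configuration
#'
#' Returns the default study conditions, overridden by any named arguments.
#' Validation errors are raised before any sampling.
#'
#' @param ... named overrides of the defaults listed below
#' @return a `sim_config` list
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 8000L,
    n_replicates = 3L,
    seed = 1L,
    length_log_mean = log(2000),
    length_log_sd = 0.7,
    cds_fraction_mean = 0.5,
    trap_log_mean = log(10),
    trap_log_sd = 1.5,
    depth_clip = 2e6,
    depth_trap = 2e7,
    slope_b = 1.0,
    dispersion_alpha = 0.1,
    trap_dispersion = 0.01,
    background_fraction = 0.1,
    target_fraction = 0.05,
    binding_factor_log2_mean = 2,
    binding_factor_log2_sd = 0.5,
    ko_coupling_gamma = 0.15,
    ko_noise_sd = 0.05,
    shared_target_fraction = 0.5,
    size_factor_log_sd = 0.2,
    min_length = 200L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop_contract("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, ov)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_contract("sim_config: ", msg)
  chk(cfg$n_genes >= 1, "n_genes must be >= 1")
  chk(cfg$n_replicates >= 1, "n_replicates must be >= 1")
  chk(cfg$cds_fraction_mean > 0 && cfg$cds_fraction_mean < 1,
      "cds_fraction_mean must be in (0,1)")
  chk(cfg$background_fraction >= 0 && cfg$background_fraction < 1,
      "background_fraction must be in [0,1)")
  chk(cfg$target_fraction >= 0 && cfg$target_fraction <= 1,
      "target_fraction must be in [0,1]")
  chk(cfg$shared_target_fraction >= 0 && cfg$shared_target_fraction <= 1,
      "shared_target_fraction must be in [0,1]")
  chk(cfg$dispersion_alpha >= 0, "dispersion_alpha must be >= 0")
  chk(cfg$trap_dispersion >= 0, "trap_dispersion must be >= 0")
  chk(cfg$depth_clip > 0 && cfg$depth_trap > 0, "depths must be positive")
  invisible(cfg)
}

#' Load a simulation configuration from YAML
#'
#' @param path YAML file whose keys are `sim_config()` fields
#' @return a `sim_config` list
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

# NB sampler that degrades to Poisson at alpha = 0
rnb <- function(n, mu, alpha) {
  if (alpha <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

sim_transcriptome <- function(cfg) {
  n <- cfg$n_genes
  with_seed(stage_seed(cfg$seed, "transcriptome"), {
    len <- pmax(cfg$min_length,
                as.integer(round(rlnorm(n, cfg$length_log_mean, cfg$length_log_sd))))
    # Beta(a, b) with mean cds_fraction_mean, modest spread
    a <- cfg$cds_fraction_mean * 10
    b <- (1 - cfg$cds_fraction_mean) * 10
    frac <- stats::rbeta(n, a, b)
    cds_len <- pmax(30L, as.integer(round(frac * len)))
    cds_len <- pmin(cds_len, len - 6L)  # leave room for UTRs
    utr5 <- as.integer(round(runif(n) * (len - cds_len)))
    id <- sprintf("tx%05d", seq_len(n))
    data.frame(
      transcript_id = id,
      gene_id = sprintf("gene%05d", seq_len(n)),
      length = len,
      cds_start = utr5,
      cds_end = utr5 + cds_len,
      cds_length = cds_len,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a complete single-cell-type experiment
#'
#' @param config a [sim_config()] list
#' @return a list with elements `txome` (transcriptome), `abundance` (long
#'   table: transcript_id, condition WT/KO, replicate, rpkm, cds_count),
#'   `counts` (long table: transcript_id, replicate, library cre_pos/cre_neg,
#'   cds_count, full_count), and `truth` (transcript_id, is_target,
#'   binding_factor_log2, true_ko_lfc, abundance, size_factors attribute)
#' @export
simulate_experiment <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  txome <- sim_transcriptome(cfg)
  n <- nrow(txome)
  k <- cfg$n_replicates

  ab <- with_seed(stage_seed(cfg$seed, "abundance"),
                  rlnorm(n, cfg$trap_log_mean, cfg$trap_log_sd))

  truth <- with_seed(stage_seed(cfg$seed, "truth"), {
    is_target <- runif(n) < cfg$target_fraction
    bf <- ifelse(is_target,
                 rnorm(n, cfg$binding_factor_log2_mean, cfg$binding_factor_log2_sd),
                 0)
    lfc <- -cfg$ko_coupling_gamma * bf + rnorm(n, 0, cfg$ko_noise_sd)
    data.frame(
      transcript_id = txome$transcript_id,
      is_target = is_target,
      binding_factor_log2 = bf,
      true_ko_lfc = lfc,
      abundance = ab,
      stringsAsFactors = FALSE
    )
  })

  sf <- with_seed(stage_seed(cfg$seed, "size_factors"),
                  rlnorm(k, 0, cfg$size_factor_log_sd))

  # expected CLIP means: power law in abundance x binding factor x CDS length
  base_nobind <- ab^cfg$slope_b * txome$cds_length / 1e3
  base_bind <- base_nobind * 2^truth$binding_factor_log2
  c_scale <- cfg$depth_clip / sum(base_bind)
  counts <- with_seed(stage_seed(cfg$seed, "clip_counts"), {
    out <- vector("list", 2L * k)
    for (j in seq_len(k)) {
      mu_pos <- sf[j] * c_scale * base_bind
      mu_neg <- cfg$background_fraction * sf[j] * c_scale * base_nobind
      pos <- rnb(n, mu_pos, cfg$dispersion_alpha)
      neg <- rnb(n, mu_neg, cfg$dispersion_alpha)
      rep_id <- sprintf("rep%d", j)
      out[[2L * j - 1L]] <- data.frame(
        transcript_id = txome$transcript_id, replicate = rep_id,
        library = "cre_pos", cds_count = pos, full_count = pos,
        stringsAsFactors = FALSE)
      out[[2L * j]] <- data.frame(
        transcript_id = txome$transcript_id, replicate = rep_id,
        library = "cre_neg", cds_count = neg, full_count = neg,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })

  # TRAP: WT abundance ab, KO = ab * 2^lfc; RPKM with replicate noise via NB
  trap_scale <- cfg$depth_trap / sum(ab * txome$cds_length / 1e3)
  abundance <- with_seed(stage_seed(cfg$seed, "trap"), {
    out <- vector("list", 2L * k)
    for (j in seq_len(k)) {
      rep_id <- sprintf("rep%d", j)
      for (cond in c("WT", "KO")) {
        mean_ab <- if (cond == "WT") ab else ab * 2^truth$true_ko_lfc
        mu <- trap_scale * mean_ab * txome$cds_length / 1e3
        cnt <- rnb(n, mu, cfg$trap_dispersion)
        # RPKM from the sampled counts, on the CDS basis
        rpkm <- cnt * 1e9 / (txome$cds_length * sum(cnt))
        out[[(j - 1L) * 2L + (cond == "KO") + 1L]] <- data.frame(
          transcript_id = txome$transcript_id, condition = cond,
          replicate = rep_id, rpkm = rpkm, cds_count = cnt,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  attr(abundance, "region_basis") <- "cds"
  attr(truth, "size_factors") <- sf

  list(txome = txome, abundance = abundance, counts = counts, truth = truth)
}

#' Simulate a two-cell-type experiment with partially overlapping targets
#'
#' Both cell types share the transcriptome and underlying abundance. Targets
#' are partitioned into shared, A-specific and B-specific sets:
#' `shared_target_fraction` of targets carry their binding factor in both
#' cell types; the rest are split evenly between A-only and B-only.
#'
#' @param config a [sim_config()] list
#' @return list with elements `a` and `b` (each as [simulate_experiment()])
#'   plus `truth` carrying `cell_type_membership` in
#'   `{"shared", "a_only", "b_only", "none"}`
#' @export
simulate_two_celltypes <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  txome <- sim_transcriptome(cfg)
  n <- nrow(txome)
  k <- cfg$n_replicates

  ab <- with_seed(stage_seed(cfg$seed, "abundance"),
                  rlnorm(n, cfg$trap_log_mean, cfg$trap_log_sd))

  truth <- with_seed(stage_seed(cfg$seed, "truth2"), {
    is_target <- runif(n) < cfg$target_fraction
    idx <- which(is_target)
    idx <- idx[sample.int(length(idx))]
    n_sh <- round(cfg$shared_target_fraction * length(idx))
    n_rest <- length(idx) - n_sh
    n_a <- ceiling(n_rest / 2)
    member <- rep("none", n)
    member[idx[seq_len(n_sh)]] <- "shared"
    if (n_a > 0) member[idx[n_sh + seq_len(n_a)]] <- "a_only"
    if (n_rest - n_a > 0)
      member[idx[n_sh + n_a + seq_len(n_rest - n_a)]] <- "b_only"
    bf <- ifelse(is_target,
                 rnorm(n, cfg$binding_factor_log2_mean, cfg$binding_factor_log2_sd),
                 0)
    data.frame(
      transcript_id = txome$transcript_id,
      is_target = is_target,
      binding_factor_log2 = bf,
      cell_type_membership = member,
      abundance = ab,
      stringsAsFactors = FALSE
    )
  })

  sim_counts_for <- function(bf_vec, stage) {
    base_nobind <- ab^cfg$slope_b * txome$cds_length / 1e3
    base_bind <- base_nobind * 2^bf_vec
    c_scale <- cfg$depth_clip / sum(base_bind)
    sf <- with_seed(stage_seed(cfg$seed, paste0(stage, "_sf")),
                    rlnorm(k, 0, cfg$size_factor_log_sd))
    with_seed(stage_seed(cfg$seed, paste0(stage, "_counts")), {
      out <- vector("list", 2L * k)
      for (j in seq_len(k)) {
        mu_pos <- sf[j] * c_scale * base_bind
        mu_neg <- cfg$background_fraction * sf[j] * c_scale * base_nobind
        pos <- rnb(n, mu_pos, cfg$dispersion_alpha)
        neg <- rnb(n, mu_neg, cfg$dispersion_alpha)
        rep_id <- sprintf("rep%d", j)
        out[[2L * j - 1L]] <- data.frame(
          transcript_id = txome$transcript_id, replicate = rep_id,
          library = "cre_pos", cds_count = pos, full_count = pos,
          stringsAsFactors = FALSE)
        out[[2L * j]] <- data.frame(
          transcript_id = txome$transcript_id, replicate = rep_id,
          library = "cre_neg", cds_count = neg, full_count = neg,
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
  }

  bf_a <- ifelse(truth$cell_type_membership %in% c("shared", "a_only"),
                 truth$binding_factor_log2, 0)
  bf_b <- ifelse(truth$cell_type_membership %in% c("shared", "b_only"),
                 truth$binding_factor_log2, 0)

  wt_abundance <- function(stage) {
    trap_scale <- cfg$depth_trap / sum(ab * txome$cds_length / 1e3)
    with_seed(stage_seed(cfg$seed, stage), {
      out <- vector("list", k)
      for (j in seq_len(k)) {
        mu <- trap_scale * ab * txome$cds_length / 1e3
        cnt <- rnb(n, mu, cfg$trap_dispersion)
        rpkm <- cnt * 1e9 / (txome$cds_length * sum(cnt))
        out[[j]] <- data.frame(
          transcript_id = txome$transcript_id, condition = "WT",
          replicate = sprintf("rep%d", j), rpkm = rpkm, cds_count = cnt,
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
  }

  list(
    a = list(txome = txome, counts = sim_counts_for(bf_a, "cellA"),
             abundance = wt_abundance("trapA")),
    b = list(txome = txome, counts = sim_counts_for(bf_b, "cellB"),
             abundance = wt_abundance("trapB")),
    truth = truth
  )
}

#' Simulate uniform read coverage over transcripts
#'
#' Read start positions are uniform on each transcript (constrained so the
#' read fits); the per-transcript read count is exact. Used as the flatness
#' fixture for metagene profiling.
#'
#' @param txome transcriptome data frame
#' @param reads_per_transcript exact number of reads per transcript
#' @param read_length read length in nt
#' @param seed RNG seed
#' @param replicate,library labels stamped on the tags
#' @return tag data frame (`transcript_id`, `start`, `end`, `replicate`,
#'   `library`)
#' @export
simulate_uniform_coverage <- function(txome, reads_per_transcript, read_length,
                                      seed, replicate = "rep1",
                                      library = "cre_pos") {
  validate_transcriptome(txome)
  too_short <- txome$length < read_length
  if (any(too_short)) {
    warning(sum(too_short), " transcript(s) shorter than read_length; skipped",
            call. = FALSE)
    txome <- txome[!too_short, , drop = FALSE]
  }
  n <- nrow(txome)
  with_seed(seed, {
    starts <- lapply(seq_len(n), function(i) {
      as.integer(floor(runif(reads_per_transcript,
                             0, txome$length[i] - read_length + 1)))
    })
    data.frame(
      transcript_id = rep(txome$transcript_id, each = reads_per_transcript),
      start = unlist(starts),
      end = unlist(starts) + read_length,
      replicate = replicate,
      library = library,
      stringsAsFactors = FALSE
    )
  })
}

#' Write the outputs of [simulate_experiment()] to a directory
#'
#' Emits `txome.bed12`, `counts.tsv`, `abundance.tsv` and `truth.tsv`.
#'
#' @param sim result of [simulate_experiment()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_annotation_bed12(sim$txome, file.path(dir, "txome.bed12"))
  write_tsv_atomic(sim$counts, file.path(dir, "counts.tsv"))
  write_tsv_atomic(sim$abundance, file.path(dir, "abundance.tsv"))
  write_tsv_atomic(sim$truth[c("transcript_id", "is_target",
                               "binding_factor_log2", "true_ko_lfc")],
                   file.path(dir, "truth.tsv"))
  invisible(dir)
}
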