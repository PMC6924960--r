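# clipscore

Cell-type-specific CLIP (UV cross-linking and immunoprecipitation) measures
where an RNA-binding protein touches RNA in vivo, but raw CLIP tag counts
mostly reflect how abundant each transcript is, not how avidly it is bound.
`clipscore` implements an abundance-normalized quantification of
coding-region binding for conditional-tag (cTag) CLIP experiments in which a
Cre-positive library carries the cell-type-specific signal and a matched
Cre-negative library measures nonspecific background, and cell-type-matched
ribosome-bound abundance (TRAP/RiboTag, or FACS RNA-seq) provides the
expression reference.

The package is aimed at analysts of RBP cTag CLIP experiments (the motivating
system is FMRP binding in hippocampal neurons) who have per-transcript tag
counts and abundance tables and want target calls, significance estimates and
downstream regulation analyses without re-deriving the statistics.

## The model

For transcript *i* and replicate *j*, the background-subtracted coding-region
tag density is

    RPKM_ij = (CrePos_ij − CreNeg_ij) × 10^9
              ─────────────────────────────────────────────
              CDSLength_i × (TotalCrePos_j − TotalCreNeg_j)

with RPKM set to 1 when the background count reaches the signal count or both
are zero. Because tag density scales with expression, each replicate gets an
ordinary least-squares fit of log2 CLIP RPKM on log2 abundance RPKM (over
transcripts with ≥1 Cre-positive CDS tag), and the **CLIP score** is the
residual

    score_ij = log2 RPKM_ij − (slope_j · log2 A_i + intercept_j)

i.e. binding relative to similarly expressed transcripts. Transcripts are
classified as **stringent** (score ≥ 2 in every replicate), **high** (mean
score ≥ 1), **low** (mean in [0, 1)) or non-targets.

Around this core the package provides:

* a count-scale variant that models background-subtracted CLIP CDS counts as
  negative binomial (variance μ + αμ²) with μ from a log-log count regression
  and α from a method-of-moments dispersion trend α(μ) = a0/μ + a1; one-sided
  tail p-values per replicate, Fisher-combined, BH-adjusted;
* metagene coverage profiles around start/stop codons with per-transcript
  equal weighting and structural-representation normalization;
* KO-vs-WT regulation analysis: median-of-ratios size factors, paired log2
  fold changes, class-wise CDF-shift (KS) tests, length/abundance-matched
  control sampling and Wilcoxon gene-set comparisons;
* cross-cell-type differential binding with a moderated t statistic and the
  joint filter (≥1 tag in every replicate of both cell types, calls requiring
  adjusted p ≤ 0.05 and mean score ≥ 0 in at least one cell type);
* a synthetic-data generator with known ground truth (planted binding
  factors, KO coupling, two cell types) so every stage is testable offline.

## Worked example

```r
library(clipscore)

sim <- simulate_experiment(sim_config(n_genes = 8000, seed = 11))
res <- clip_score_pipeline(sim$counts, sim$abundance, sim$txome)

table(res$table$target_class)
#>  stringent       high        low non_target
#>        125        323       3023       4529

sapply(res$fits, function(f) c(slope = f$slope, r2 = f$r_squared))
#>             rep1      rep2      rep3
#> slope  1.0022518 0.9965107 0.9989900
#> r2     0.8573247 0.8604696 0.8572364

rank_auc(res$table$mean_clip_score, sim$truth$is_target)
#> [1] 0.9945419
```

The slope near 1 says CLIP tag density scales proportionally with abundance
in this simulation; the residual scores then rank the planted targets almost
perfectly (AUC 0.99), and about 2% of transcripts reach the stringent class.

A shell entry point wrapping the same functions is installed at
`inst/scripts/clipscore`:

```sh
Rscript inst/scripts/clipscore simulate --out-dir sim/ --seed 11
Rscript inst/scripts/clipscore score --counts sim/counts.tsv \
    --abundance sim/abundance.tsv --annotation sim/txome.bed12 --out scores.tsv
```

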