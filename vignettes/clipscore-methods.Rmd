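---
title: "Methods: abundance-normalized CLIP quantification in clipscore"
author: "clipscore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abundance-normalized CLIP quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical methods: the
models, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, the numerical choices made at genuinely
open design points, and the known limitations.

## 1. The CLIP score model

A conditional-tag CLIP experiment yields, per biological replicate, a
Cre-positive library (cell-type-specific signal plus nonspecific capture)
and a Cre-negative library (nonspecific capture only). Because both are
indexed, pooled and amplified together, their relative depths are
meaningful, and background subtraction can be done on raw counts. For
transcript $i$, replicate $j$:

$$\mathrm{RPKM}_{ij} = \frac{(\mathrm{CrePos}_{ij} - \mathrm{CreNeg}_{ij})
\times 10^9}{L^{CDS}_i \,(\mathrm{TotalCrePos}_j - \mathrm{TotalCreNeg}_j)}$$

with the sentinel value 1 (log2 = 0) whenever the background count is at
least the signal count, or both are zero. The analysis is deliberately
restricted to the coding region, where the motivating RBP (FMRP, a
polysome-associated translational regulator) acts.

Tag density grows with transcript abundance, so raw RPKM mostly ranks
expression. Each replicate therefore receives an OLS fit of
$\log_2 \mathrm{RPKM}_{ij}$ on $\log_2 A_i$ (abundance RPKM from TRAP, or
FACS RNA-seq through the same code path), over transcripts with at least one
Cre-positive CDS tag. The CLIP score is the residual:

$$\mathrm{score}_{ij} = \log_2 \mathrm{RPKM}_{ij} -
(\hat\beta_j \log_2 A_i + \hat\alpha_j)$$

computed for *every* transcript, including tag-free ones (whose sentinel
RPKM yields strongly negative scores at high abundance — evidence of
*non*-binding). Classification: **stringent** if score ≥ 2 in all
replicates; otherwise **high** if the mean score ≥ 1; **low** if the mean is
in [0, 1); otherwise non-target. A transcript with any missing replicate
score (non-positive abundance) is a flagged non-target.

Assumptions worth stating: (i) a single power-law relation between CLIP
density and abundance holds across the expressed transcriptome — the
regression is global, not local; (ii) background is adequately modelled by
paired subtraction, i.e. nonspecific capture is proportional to the
Cre-negative library and not binding-dependent; (iii) the CDS length
normalization assumes binding opportunity scales with coding length.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `stringent_min` | 2 (log2 units) | per-replicate threshold, all replicates |
| `high_min` | 1 (log2 units) | mean-score threshold |
| `include_sentinel` | `TRUE` | keep sentinel-RPKM transcripts in the fit |
| `min_rpkm` | 1 (RPKM) | expression filter in principal-transcript selection |

The stringent rule is stated ambiguously in the field's descriptions (≥ 2
versus > 2); the package uses ≥ 2, configurable, and ties at exactly 2.0 are
vanishingly rare on continuous scores. Whether transcripts whose RPKM
collapsed to the sentinel should enter the regression is genuinely open: with
`include_sentinel = TRUE` (default) every tagged transcript informs the fit,
at the cost of a mild downward pull at low abundance; `FALSE` drops them.
Both are exposed because neither choice is derivable from first principles.

## 2. The count-based negative-binomial variant

RPKM subtraction discards count-level uncertainty: a score of 1.5 from 3
tags and from 300 tags carry very different evidence. The count variant
models the background-subtracted CLIP CDS count $X_i$ (floored at 0) as
negative binomial with mean $\mu_i$ and dispersion $\alpha$
($\mathrm{Var} = \mu + \alpha\mu^2$):

* $\mu_i$ per replicate comes from an OLS fit of $\log X$ on
  $\log(\mathrm{TRAP\ CDS\ count})$ over transcripts with positive
  subtracted counts, exponentiated at each transcript's TRAP count. Fit
  exclusion applies to the regression only — every expressed transcript is
  scored.
* $\alpha$ comes from replicate variability: per-transcript
  method-of-moments estimates $\hat\alpha_i = \max(0, (s^2_i - m_i)/m^2_i)$,
  then a parametric trend $\alpha(\mu) = a_0/\mu + a_1$ fitted by
  iteratively reweighted least squares ($1/\mathrm{fitted}^2$ weights, the
  Gamma-family variance weighting). The dispersion used for testing is the
  trend value at the transcript's fitted mean; there is no per-gene
  empirical-Bayes shrinkage, which keeps the estimator self-contained and
  testable. When the trend cannot be fit, the median positive raw estimate
  is used with a warning.
* the one-sided p-value is $P(X \ge x_{obs})$ (so $p(0)=1$ exactly), with
  the Poisson limit at $\alpha = 0$; replicate p-values are combined by
  Fisher's method ($\chi^2 = -2\sum\ln p$, $2k$ df; zero p-values are
  clipped to the smallest positive double, never dropped) and converted to
  FDR by Benjamini–Hochberg over the analysis set (≥1 positive subtracted
  count across replicates).

**Calibration caveat.** The $\mu$ estimator is the exponential of a
log-scale fit, i.e. a conditional *geometric* mean. For a skewed count
distribution this undershoots the arithmetic mean by roughly
$e^{\sigma^2/2}$, which makes the one-sided tail mildly anti-conservative:
under the package's null generator the empirical
$P(p_{\mathrm{combined}} < 0.05)$ is ≈ 0.04–0.09 depending on the
realization of the dispersion-trend fit, and exact uniformity of combined
p-values is not achieved (the test statistic is discrete and the plug-in
$\hat\mu,\hat\alpha$ carry estimation error; a KS test against the uniform
rejects at transcriptome scale). The variant is therefore best read as a
*ranking* statistic with approximate error control; the test suite measures
both properties rather than assuming them. Empirically the count-based
scores rank-correlate with the RPKM-based scores at Spearman ρ ≈ 0.97.

## 3. Coverage profiles

Per-transcript coverage counts tag intervals per nucleotide. The genic
distribution assigns each read by the position of its center —
`floor((start + end)/2)`, an explicit choice for even-length reads — to
5'UTR, CDS or 3'UTR (transcript-space annotation has no introns; the class
is kept, structurally empty, for interface completeness), normalized by the
total feature length across the annotation.

The metagene profile answers "where on the message does the protein sit?"
while preventing a handful of heavily tagged transcripts from dominating:

1. rank transcripts by whole-transcript tag density, keep the `top_n`
   (default 1000) densest;
2. give each read a signed offset of its center from the anchor — the first
   nucleotide of the start codon (`cds_start`) or of the stop codon
   (`cds_end - 3`; the registration is a documented choice);
3. keep reads with offsets in `[-flank_nt, flank_nt)`;
4. weight each kept read by $1/R_t$ ($R_t$ = kept reads of its transcript),
   so every contributing transcript carries total mass exactly 1;
5. sum weights in 10-nt bins, then divide each bin by the fraction of the
   `top_n` transcripts whose structure fully contains that window
   ("representation"), since short UTRs/CDSs cannot cover distal bins. The
   representation denominator is structural (is the transcript long
   enough?), not observational (did it have reads there?) — the latter
   reading would cancel real coverage gradients. Bins with zero
   representation are emitted as missing.

On uniform synthetic coverage the normalized profile is flat to a
coefficient of variation of about 3–4% at 200 transcripts × 500 reads,
which is the package's flatness regression test.

## 4. KO regulation and matched controls

The KO-vs-WT analysis uses a deliberately simple fold-change estimator:
median-of-ratios size factors (the standard library-size estimator for
count data), then the mean over paired replicates of
$\log_2((\mathrm{KO}/f + 1)/(\mathrm{WT}/f + 1))$. This is a documented
stand-in for a full shrinkage-based differential-expression fit; an adapter
accepts externally computed per-transcript LFC tables so real-data users can
substitute one. The pseudocount of 1 normalized count stabilizes
low-expression ratios at the cost of shrinking them toward 0.

Class-wise regulation structure is tested by two-sample two-sided
Kolmogorov–Smirnov comparisons of LFC distributions (each target class
against non-targets, and adjacent classes), with classes under 5 members
skipped. Matched controls are drawn by stratified sampling: targets are
binned into deciles of log10 length (and/or log10 abundance; both gives the
joint grid), and one control per target is drawn without replacement from
the pool's same bin, falling back to the nearest non-empty bin with a log
message. Decile strata were chosen over nearest-neighbor matching for
determinism and simplicity; with the default bin count the control length
distribution is statistically indistinguishable from the targets' (KS
p > 0.9 in the packaged runs). When abundance matching is on, both targets
and pool are first restricted to an RPKM window (default [10, 200]) so that
controls exist across the matched range.

**A caveat the tests surfaced.** The CLIP score and the KO/WT fold change
share the same measured WT abundance replicates: WT measurement noise enters
the score with a negative sign (normalization) and the LFC with a negative
sign (denominator), inducing a small positive correlation between score and
LFC among unbound transcripts (≈ +0.03 median LFC for the low class at the
default simulation depths). Consequently the low class — which under the
generator's bimodal binding model contains almost no true binders — sits
slightly *above* the non-target class, and at class sizes in the thousands a
KS test detects this coupling even when the KO effect is switched off
entirely. The stringent and high classes, where true binding dominates, show
the expected strong downward shifts (median LFC ≈ −0.33 and −0.24 at the
default KO coupling, KS p < 10⁻¹⁵). Real experiments face the same shared-
noise structure whenever the same TRAP libraries normalize CLIP and define
the fold change; the effect size here bounds how small a CDF shift one
should be willing to interpret.

The behavioral discrimination index `(d − u)/(d + u)` with a 5-second
total-exploration exclusion is included as a self-contained utility for the
memory-task readout associated with this experimental system.

## 5. Differential binding across cell types

Transcripts are compared only if they have ≥ 1 Cre-positive CDS tag in
*every* replicate of *both* cell types — the subset where per-replicate
scores are all data-driven rather than sentinel-derived. Replicate scores
are compared with a two-group moderated t: per-transcript pooled variances
$s^2_g$ (d = n_a + n_b − 2 df) are shrunk toward a common prior
$(s_0^2, d_0)$ estimated by method of moments on the log-variance scale
(matching the mean and variance of $\log s^2$ under a scaled-F model, with
the trigamma function inverted by Newton iteration), giving

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},\qquad
t_g = \frac{\bar y_{a,g} - \bar y_{b,g}}{\tilde s_g \sqrt{1/n_a + 1/n_b}}$$

on $d + d_0$ df. At $d_0 = 0$ this is exactly the ordinary pooled t (a
tested limit); the estimator agrees with the reference empirical-Bayes
implementation (limma) at Spearman ρ > 0.99 on shared input. Calls require
BH-adjusted p ≤ 0.05 *and* mean score ≥ 0 in at least one cell type — the
second filter removes "differences" between two degrees of non-binding. The
design is unpaired two-group; replicate pairing across cell types is not
assumed.

## 6. The synthetic-data generator

The generator is first-class, tested code that defines the package's study
conditions. Per transcript: length log-normal (meanlog log 2000, sdlog 0.7
— a realistic mRNA length spread); CDS fraction Beta-distributed around
0.5; abundance $A_i$ log-normal (meanlog log 10, sdlog 1.5, spanning ~0.1
to ~1000 RPKM). A fraction `target_fraction` (default 0.05) of transcripts
are true targets with binding factor $b_i \sim N(2, 0.5)$ in log2 units;
non-targets have $b_i = 0$. CLIP counts are NB with mean
$s_j\, c\, A_i^{\beta}\, 2^{b_i} L^{CDS}_i/10^3$ (slope $\beta = 1$,
dispersion 0.1 — typical for CLIP replicate scatter), replicate size
factors $s_j$ log-normal (sd 0.2) to exercise the depth normalization, and
totals scaled to 2 × 10⁶ tags. Cre-negative background is NB at
`background_fraction` (0.1) of the *binding-free* mean — nonspecific
capture does not see the binding factor. TRAP counts are NB (dispersion
0.01, depth 2 × 10⁷) around $A_i$ (WT) or $A_i 2^{\mathrm{lfc}_i}$ (KO)
with $\mathrm{lfc}_i = -\gamma b_i + N(0, 0.05)$, $\gamma = 0.15$ —
down-regulation proportional to binding, the hallmark the regulation module
must detect. The two-cell-type variant splits targets into shared (50%),
A-only and B-only sets over a common transcriptome and abundance.

Sampling is driven by per-stage streams derived from one run seed, so a
fixed seed gives byte-identical outputs and partial re-runs are stable.

What the generator does *not* emulate: sequence content and motifs, UTR
binding, spliced genomic coordinates, alignment and PCR-duplicate
artifacts, binding-dependent background, and continuous (rather than
bimodal) binding-affinity spectra. Passing tests therefore demonstrate that
the estimators recover the parameters of this generative model — not that
the model captures every property of a real CLIP library.

## 7. Numerical and edge-case choices

* Transcript coordinates are 0-based half-open throughout; BED is native,
  GTF is converted on read.
* CDS overlap counting uses a ≥ 1-nt rule.
* Principal-transcript ties (equal mean RPKM) go to the lexicographically
  smaller transcript id.
* Non-positive abundance yields missing scores, never zeros — missingness
  propagates to a flagged non-target rather than inventing signal.
* The NB p-value includes the observed count in the tail; dispersion 0
  routes to the exact Poisson tail.
* Fisher's method clips p = 0 to `.Machine$double.xmin` rather than
  dropping replicates.
* Wilcoxon comparisons use exact enumeration for combined n ≤ 20 without
  ties, otherwise the normal approximation with tie correction.
* Problem sizes in the packaged checks (8000-transcript simulations,
  5000-transcript null calibration, 200 × 500 metagene fixture) were chosen
  as the smallest sizes at which the measured quantities stabilize.

## 8. Known limitations

* The count-variant's error control is approximate (Section 2); FDR values
  near the threshold should not be over-read.
* The dispersion trend assumes a monotone $a_0/\mu + a_1$ shape; strongly
  non-monotone mean–dispersion relationships would be mis-fit.
* Matching uses marginal/joint decile strata, not optimal transport; in
  pathological pools the nearest-bin fallback can relax match quality (it
  is logged when it happens).
* The moderated t assumes approximately normal replicate scores; scores
  built from very low counts are noticeably non-normal, which is partly
  mitigated by the shared-transcript filter.
* One transcript per gene: isoform-level binding differences are invisible
  by construction.
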