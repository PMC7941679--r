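---
title: "Chromosome-scale length variation risk modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-scale length variation risk modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cslvrisk)
```

## The model

A germline SNP-array copy-number pipeline reports, per sample, a set of
segments: a chromosome, a start and end position (1-based, inclusive), and a
*segment mean* — the log base 2 of one-half the copy number of that
interval. Diploid intervals have segment mean 0; a segment mean *m*
corresponds to `2 * 2^m` copies and a relative chromosome-length change of
`2^m - 1`.

`cslvrisk` compresses each sample's segments into one value per chromosome,
the chromosome-scale length variation (CSLV): the length-weighted mean of
the segment means,

$$\mathrm{CSLV}_{ic} \;=\; \frac{\sum_s w_s m_s}{\sum_s w_s},$$

with weights $w_s = \mathrm{end}_s - \mathrm{start}_s + 1$. The weighted
mean is the unique aggregator with *refinement invariance*: splitting a
segment into contiguous sub-segments with the same mean cannot change the
value, so the result does not depend on how finely the upstream segmenter
happened to cut. Unreported regions contribute nothing — they are **not**
imputed as diploid, and a chromosome with no reported segments is an
explicit missing value. The covered fraction of each chromosome is always
recorded, and `min_coverage` (default 0, i.e. use whatever is reported)
suppresses values computed from thin coverage; setting it to 0.9 restricts
the feature to near-whole-chromosome reports. Probe-count weighting
($w_s$ = number of probes) is available behind a flag for pipelines where
probe density, not genomic span, is the natural weight; length weighting is
the default because it is the one with a direct physical reading (average
excess length of the chromosome).

The feature set defaults to the 22 autosomes. Chromosome X can be included
by configuration (`grch38_chromosome_lengths(include_x = TRUE)`); it is off
by default because X copy number is confounded with sex in mixed cohorts,
and the package's target design is single-sex. The GRCh38 primary-assembly
lengths ship with the package so coverage fractions never require a
download; a different length table can be passed in.

Samples are labelled case/control from a clinical table, joined on the
sample identifier, with germline (blood-derived normal) samples
identifiable through the TCGA barcode convention (sample-type code `"10"`).
The default inclusion filter keeps female subjects only. Rows whose entire
feature vector is missing are excluded — they carry no ranking information —
and every exclusion is tallied under exactly one reason.

## Scoring and stratification

Risk scores are out-of-fold probabilities from stratified k-fold
cross-validation (default k = 5): each fold is scored by a model trained on
the other folds, so no sample's features influence its own score. The
default learner is a gradient-boosting machine at its stock configuration —
maximum depth 5, sample rate 1.0 — with tree count 100 and learning rate 0.1
fixed and documented rather than auto-tuned; random forests, extremely
randomized trees and a linear-logistic baseline plug into the same
interface for family comparison, always on one shared fold assignment so
family differences are not fold noise. Folds are stratified by label by
default: at ~9% prevalence, unstratified folds risk training splits with
almost no cases at small n. Missing features use the learner's native
handling when it has one (gradient boosting); otherwise per-column medians
are fit on the training split only, so imputation cannot leak test
information, with an all-missing column falling back to 0 (the diploid
value).

For stratification, samples are ranked by score (ties broken by sample
identifier — a stable, auditable policy) and cut into B bins whose sizes
differ by at most one, the remainder going to the lowest-score bins
(4639 samples in 5 bins gives 928/928/928/928/927). Each bin is summarized
by its odds ratio *relative to the entire cohort*,
$(a/b)\,/\,(c/d)$, taken literally (bin versus whole cohort, overlapping)
rather than bin-versus-rest — the literal reading is the one consistent
with published quintile tables of this design; bin-versus-rest can be
obtained from the same counts if wanted. The 95% CI is Wald on the log-OR
scale with $SE = \sqrt{1/a + 1/b + 1/c + 1/d}$ and the *unrounded* OR;
`round_or` exists because some published displays round the point estimate
before exponentiating, which changes the printed bounds for tiny ORs. Zero
cells make the OR (b = 0) or CI (any cell) undefined, flagged rather than
silently corrected; an explicit 0.5 continuity correction is behind a flag.
Because everything depends on the scores only through ranks, all stratum
output is invariant under strictly increasing transforms of the score.

The AUC is computed as the Mann-Whitney rank statistic (ties count one
half), which equals the trapezoidal area under the empirical ROC curve
exactly; its CI is a stratified percentile bootstrap (default 2000
resamples, cases and controls resampled separately). The single-split
(80/20, stratified) model supports ROC display and attribution.
Attributions for tree models are additive SHAP-style contributions on the
margin (log-odds) scale, per sample and chromosome, summing with the
baseline to the prediction; other families fall back to permutation
importance, where only the mean-|effect| ranking is meaningful.

## The synthetic generator

The generator stands in for controlled germline data. For subject *i* and
chromosome *c* it draws a latent copy number
$cn_{ic} = 2 + \mathrm{case}_i\,\beta_c + \varepsilon_{ic}$,
$\varepsilon \sim N(0, \sigma_b)$, truncated below at 0.1 copies; splits the
chromosome at uniform breakpoints into 1–4 segments; reports each segment
mean as $\log_2(cn_{ic}/2)$ plus $N(0, \sigma_m)$ noise; and withholds the
whole chromosome with probability `missing_prob` (all-or-nothing dropout,
matching the N/A coding of real masked tables). Its defaults are the study
conditions this package targets: 414 cases and 4225 controls, all female;
case shifts $\beta_{17} = +0.06$ and $\beta_4 = +0.03$ copies (the larger
effect on chromosome 17, so attribution recovery is testable);
$\sigma_b = 0.06$ copies; $\sigma_m = 0.01$ on the log2 scale;
`missing_prob` 0.01. Effects are parameterized in copy-number units and
passed through $\log_2(cn/2)$ so a +0.056-copy shift corresponds to a
segment mean near 0.02. The noise scales are chosen for testability — they
produce CSLV histograms of plausible width — not fitted to any real cohort.

With a single informative chromosome the model admits a closed-form optimal
AUC, $\Phi(|\beta_c| / (\sigma_b \sqrt2))$ (`analytic_auc()`): both classes
are Gaussian with common variance on the copy-number scale and the log2 map
is monotone. This oracle is what the pipeline is validated against — an
independent target the classifier code cannot influence.

What the generator does *not* emulate: probe-level array noise and GC
waves, segmentation-algorithm artefacts, batch effects, population
stratification, linkage between chromosomes, or the control-group
composition of convenience cohorts (controls drawn from patients with other
diseases). Passing tests therefore demonstrate that the pipeline's
statistics behave correctly under its assumed generative model — they do
not certify performance numbers on real cohorts.

## Numerical and validation choices

- Coordinates are 1-based inclusive throughout; segment span is
  `end - start + 1`. Overlapping segments and segments past the chromosome
  end are hard errors naming the offender, and malformed rows abort a read
  by default (a lenient flag downgrades them to counted skips) — silent
  data loss is worse than a loud failure in a case-control study.
- Conversions are validated by round-trip (copy number → segment mean →
  copy number, tolerance 1e-12), and CSLV against a brute-force per-base
  average on toy chromosomes (≤ 1e-9) plus exact refinement invariance.
- Pipeline accuracy is validated at modest problem sizes: 1000 + 1000
  subjects, one chromosome, effect/SD = √2, where the cross-validated AUC
  must land within ±0.03 of the analytic 0.841; a label-permutation null
  (20 permutations of a 400-subject cohort) must average within 0.04 of
  0.5; and group CSLV means at 500 per group must sit within 3 standard
  errors of their latent targets. These sizes make the full suite run in
  well under a minute of classifier time while leaving Monte-Carlo error
  far below the asserted bands.
- All randomness flows from named integer seeds (fold assignment, learner
  internals, bootstrap, generator); the generator restores the caller's RNG
  state, and identical configs reproduce output files byte-for-byte.
- Published quintile tables are reproduced from their printed counts at the
  table's own precision. One documented subtlety: Wald bounds reproduce
  printed intervals exactly with the unrounded OR, but the smallest bins'
  printed bounds can only be recovered by rounding the OR first — both
  behaviors are exposed, unrounded being the default and the statistically
  defensible choice.

## Limitations

The package evaluates discrimination (AUC, quantile ORs) on the cohort it
is given; it performs no age or race adjustment or matching, no
batch-effect or population-stratification correction, and no transfer
validation to an independently collected cohort — all of which matter
before any claim about a deployable risk score. Sub-chromosome (arm or
band) features and deep-learning learners are out of scope. The top-vs-
bottom quantile contrast is reported as a plain odds ratio with its Wald
CI; contrasts of extreme bins are noisy, and their CIs should be read
accordingly.
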