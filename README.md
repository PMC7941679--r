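# cslvrisk

Genetic risk scores from chromosome-scale length variation in germline
copy-number data.

## The problem

Structural variation — insertions, deletions, duplications, translocations —
slightly alters the total length of each chromosome a person carries.
SNP-array copy-number pipelines summarize this as *segment means*: for a
genomic interval, the log base 2 of one-half the copy number, so a normal
diploid interval has segment mean 0 and a segment mean of 0.02 corresponds
to 2 · 2^0.02 ≈ 2.028 copies, about 1.4% extra length. Aggregating the
segment means across a whole chromosome gives one number per chromosome per
person — the **chromosome-scale length variation (CSLV)** — and the 22
autosomal CSLV values form a compact germline feature vector for
case-control risk modelling.

`cslvrisk` is for statistical geneticists and biomedical data scientists who
want to build and evaluate such risk scores. It implements:

- **Feature extraction.** For sample *i* and chromosome *c* with reported
  segments *s* (lengths *w_s*, segment means *m_s*):
  `CSLV_ic = Σ w_s m_s / Σ w_s`, the length-weighted mean of segment means,
  with the covered fraction tracked and unreported chromosomes kept as
  explicit missing values (never imputed as diploid).
- **Risk scoring.** Out-of-fold probabilities from stratified *k*-fold
  cross-validation over pluggable learners (gradient boosting by default,
  depth 5, sample rate 1; also random forests, extremely randomized trees,
  and a linear-logistic baseline), with strict train/test separation —
  imputation, when used, is fit on training folds only.
- **Stratification.** Samples ranked by score and cut into quantile bins;
  each bin's odds ratio *relative to the entire cohort*,
  `OR = (a/b) / (c/d)` for bin counts (a, b) and cohort counts (c, d), with
  95% Wald CIs from `SE = sqrt(1/a + 1/b + 1/c + 1/d)` on the log-OR scale.
- **Evaluation.** Rank-statistic (Mann-Whitney) AUC with stratified
  bootstrap CIs, ROC curves, learner-family comparison on shared folds, and
  SHAP-style additive per-chromosome attributions for tree models.
- **Synthetic cohorts.** A generator that emulates the assumed data
  structure (case-specific copy-number shifts on chosen chromosomes,
  segmentation, measurement noise, chromosome dropout) plus a closed-form
  Bayes AUC oracle `Φ(|effect| / (σ√2))`, so the whole pipeline is testable
  without controlled genomic data.

## Worked example

A one-command synthetic demonstration (200 cases / 200 controls, planted
copy-number shifts of +0.12 copies on chromosome 17 and +0.05 on
chromosome 4 against a between-subject SD of 0.06 copies):

```r
library(cslvrisk)
res <- run_pipeline(demo_config(out_dir = "demo_out", seed = 1))

res$auc
#> [1] 0.8782
res$auc_ci
#>    ci_low   ci_high
#> 0.8434469 0.9102262

res$strata$bins_5
#>   bin n_controls n_cases n_total odds_ratio     ci_low    ci_high
#> 1   1         71       9      80  0.1267606 0.06166039  0.2605926
#> 2   2         67      13      80  0.1940299 0.10380508  0.3626757
#> 3   3         38      42      80  1.1052632 0.68351355  1.7872457
#> 4   4         21      59      80  2.8095238 1.64510488  4.7981281
#> 5   5          3      77      80 25.6666667 7.96645953 82.6939214

head(res$attribution$ranking, 3)
#>   chromosome mean_abs_contribution
#> 1      chr17             2.8877735
#> 2       chr4             0.4377229
#> 3      chr12             0.3049059

top_bottom_odds_ratio(res$strata$bins_5)
#> odds_ratio     ci_low    ci_high
#>  202.48148   52.70970  777.82170
```

Reading the output: the cross-validated AUC of 0.88 says a randomly chosen
case outscores a randomly chosen control 88% of the time. The quintile table
shows the odds of being a case in the top fifth of scores are ~26× the
whole-cohort odds, and the top-vs-bottom quintile contrast is ~200×
(wide CI — the bottom bin holds few cases). The attribution ranking recovers
chromosome 17 as the dominant feature, matching the planted effect.
`demo_out/` contains every intermediate as a tab-separated file plus a
`manifest.json` with seeds and counts; re-running the same config reproduces
all of them byte-for-byte.

Stage functions (`read_segment_file()`, `build_profiles()`,
`assemble_cohort()`, `cross_validated_scores()`, `stratify()`, `auc()`,
`feature_attribution()`, `generate_cohort()`) expose each step separately,
and every intermediate has a reader/writer pair so stages can be run and
inspected independently.

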