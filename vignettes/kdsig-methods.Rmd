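---
title: "Methods: knockdown signatures, KD scores and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knockdown signatures, KD scores and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdsig)
```

This vignette is the package's account of its statistical machinery: the
models behind each stage, the parameters that matter, the numerical
conventions chosen where several were defensible, and what the synthetic
generators do and do not establish about real data.

## The pipeline

A knockdown-signature study proceeds in four computational stages, each a
function over tabular data:

1. **Derivation** — a two-condition discovery experiment (knockdown vs
   control cell lines) yields per-gene log2 fold changes on group means;
   genes at or beyond a fold cutoff form the up/down signature.
2. **Scoring** — in an independent patient cohort, expression is z-scored
   per gene and each patient receives
   `KD = sum(z[up]) - sum(z[down])`: a high score marks a tumour whose
   transcriptome resembles the knockdown state.
3. **Stratification and survival** — patients are split by score (median,
   tertiles, fixed threshold, or a scanned best cutoff) and compared by
   Kaplan–Meier estimation and the log-rank test.
4. **Enrichment** — gene sets are tested against a ranking of cohort genes
   (preranked GSEA with a gene-permutation null).

## Signature derivation

`fold_changes()` uses group *means* (not medians): FPKM-style differential
expression conventionally compares means, and means make the swap-the-labels
antisymmetry exact. On a log2-scale matrix the fold change is the difference
of means; on a linear matrix it is `log2(mean_case / mean_ctrl)` and genes
with a non-positive group mean are excluded with a warning rather than
producing undefined ratios.

`build_signature()` applies the cutoff **inclusively**: "a 2-fold cutoff"
most naturally admits a gene at exactly 2-fold, and the convention is
configurable via `cutoff_fold`. No significance filter is applied by
default — the fold cutoff is the primary rule — but a Welch t-test with
Benjamini–Hochberg correction is available behind `q_max` for users who
want both. Raising the cutoff can only shrink the lists (monotone nesting),
which the test suite asserts.

## KD scoring

`zscore_by_gene()` standardises each gene over the cohort being scored,
with the sample SD (n − 1 denominator). The cohort itself is the reference
population: scores are comparable within a dataset, never across datasets.
This choice buys a strong structural invariant — every gene row is centred,
so KD scores sum to zero over any cohort — which the tests exploit. Genes
with zero variance are dropped with a warning (their z-score is undefined);
signature genes absent from the matrix are skipped and the per-sample
`n_up_used` / `n_down_used` columns make the shrinkage visible.

The score is a raw **sum**, not a mean: the sum is the primary definition,
and dividing by list length (available via `normalize = TRUE`) only matters
when comparing signatures of different sizes. Scores inherit three exact
invariances: per-gene shifts (absorbed by centring), per-gene rescalings
(absorbed by unit SD), and signature negation (score changes sign exactly).

Scoring is performed on the matrix in its declared scale; the package never
re-transforms silently. The `scale` attribute of `expr_matrix` exists to
make that declaration explicit at load time.

## Survival analysis

`km_estimate()` is the product-limit estimator over distinct observed
times; at a tied time, **events precede censorings** (the standard
convention: a subject censored at `t` is still at risk for an event at
`t`). `logrank_test()` accumulates, at each distinct event time,
hypergeometric expectation `d * n1 / n` and variance
`d (n1/n)(1 - n1/n)(n - d)/(n - 1)` (zero when a single subject remains),
referring `(O1 - E1)^2 / V` to chi-square on 1 df. Both agree with the
`survival` package to 1e-8 on randomised small datasets in the test suite —
a cross-check, not the implementation.

The hazard ratio is reported as the observed/expected ratio
`(O1/E1)/(O2/E2)` — the quantity Kaplan–Meier plot annotations
conventionally carry — rather than a Cox estimate. Cox regression,
multivariate adjustment and competing risks are deliberately out of scope;
the O/E ratio is an approximation and is `NA` whenever any of its four
terms is zero.

`best_cutoff()` scans every distinct score value between the 10% and 90%
quantiles, takes the threshold minimising the nominal log-rank p, and
corrects for the multiplicity of the scan by permuting the score–survival
pairing (1000 permutations by default, seeded) and recording the
permutation distribution of the *minimum* p. Minimum-p scanning inflates
type-I error severely, so the nominal p is reported only alongside its
adjusted companion. The scan is vectorised over thresholds (risk sets
depend only on the survival data, which permutations never touch), keeping
1000 permutations of a 200-patient cohort to a few seconds.

### What "worse prognosis for the low-score group" means here

The pipeline's directional claim — under a protective signature activity,
the low-score group has the inferior survival curve — is asserted in the
tests as: at every event time *of the low group*, the low curve lies at or
below the high curve, and the log-rank test rejects. Pointwise comparison at
*every* cohort event time is intentionally not used: whichever arm happens
to suffer the very first event dips one estimator step below the other
while both curves still sit near 1, so that comparison measures a coin flip
(bounded near 83% success at these effect sizes regardless of cohort size),
not the ordering of the curves.

## Preranked GSEA

`rank_genes()` orders genes by signal-to-noise (default for two-group
comparisons), Welch t statistic, or Pearson correlation with a continuous
score, with ties broken lexicographically by gene id so the ranking is
deterministic across platforms. The signal-to-noise denominator floors each
group SD at `0.2 * |group mean|` (and at 0.2 when both vanish), so it can
never divide by zero.

`enrichment_score()` is the weighted running sum: hits rise by
`|metric|^p / sum(|metric|^p over hits)`, misses fall by `1/(N - N_hits)`,
and the ES is the signed extremum of the walk, preferring the positive
deviation on an exact magnitude tie. The walk ends at zero by construction
and ES is bounded in [−1, 1], with |ES| = 1 exactly when all hits precede
all misses. Weight `p = 1` is the default, `p` configurable in {0, 1, 2}.

`gsea()` uses a **gene-permutation** null — set membership reassigned to
uniformly random rank positions of the same size — rather than phenotype
permutation: it is the only null available for preranked input and remains
usable for small cohorts, at the documented cost of treating genes as
exchangeable. NES divides the observed ES by the mean |null ES| of matching
sign; the nominal p is Laplace-corrected (never exactly zero) and flagged
when no same-sign null score exists. The permutation path is a closed-form
evaluation over hit positions, kept numerically identical to the full walk
and verified against an independent brute-force loop to 1e-12 in the test
suite. FDR across sets is not computed; per-set NES and nominal p are the
reported quantities.

## Synthetic generators

The generators exist so every downstream stage can be tested against known
truth; their defaults are the package's study conditions.

- `make_discovery()` plants 84 up- and 73 down-regulated genes among 1000,
  at 1.5 log2FC with within-group SD 0.3 on the log2 scale, 5 vs 5 samples —
  the scale of a cell-line knockdown RNA-seq contrast with a stringent
  2-fold signature. Noise is Gaussian on log2 (log-normal expression), the
  standard approximation for normalised array or FPKM-like data. At these
  settings the 2-fold builder recovers essentially all planted genes (the
  per-gene fold-change SE is ≈ 0.19, so a planted 1.5 sits ≈ 2.6 SE past
  the cutoff of 1.0).
- `make_cohort()` gives each patient a latent activity `a ~ N(0, 1)`,
  shifts up-genes by `+a * effect` and down-genes by `-a * effect`
  (default effect 1.0, SD 0.3), and draws exponential survival with hazard
  `baseline * exp(-beta * a)` plus independent exponential censoring. The
  sign convention is fixed: high activity ⇔ high KD score ⇔ low hazard, so
  the low-score group is the one with the worse prognosis. Exponential
  survival with a log-linear hazard is the simplest proportional-hazards
  generator; the observed KM figures such a study produces imply only a
  monotone score–hazard link, so nothing richer (Weibull, competing risks)
  is simulated.
- `make_marker_panel()` draws linear VIM/CDH1 values for 27 epithelial,
  19 mesenchymal and 6 EMT-intermediate lines — a typical breast-cancer
  panel. Epithelial log2 ratios centre at −2, mesenchymal at +3 (SD 0.7),
  and intermediates are drawn uniformly inside a band straddling the
  ratio-2 boundary. How real studies assign the "intermediate" label given
  a strict <2 / >2 rule is ambiguous, so the generator returns the band it
  used (`truth$band`) and `classify_emt()` accepts it explicitly as
  `intermediate_band` rather than hard-coding a guess.

All three are pure functions of their parameters and a single integer seed
(`withr::with_seed`; no global RNG state is touched).

What passing these tests does **not** show: real cohorts have correlated
genes, batch structure, library-size effects, non-proportional hazards and
informative censoring, none of which are simulated. The synthetic results
validate the *machinery* — estimator correctness, calibration, direction —
not the biological claim on any particular dataset.

## Simulation sizes and calibration checks

The test suite fixes its problem sizes as the package's own choices: the
log-rank null calibration uses 1000 replicate 100-patient cohorts (rejection
rate at α = 0.05 checked against the 99% binomial band [0.032, 0.068]); the
directionality check uses 50 replicate 200-patient cohorts at beta = 1; the
GSEA null calibration uses 200 replicates of a 200-gene ranking with 500
permutations each (KS test against uniform at α = 0.01); the best-cutoff
null uniformity check runs at a reduced 60 replicates of 60 patients with
99 permutations. `scripts/acceptance.R` re-runs the same computations from
a caller-supplied seed.

## Numerical conventions, collected

- Fold cutoff boundary: inclusive; configurable.
- Median-split ties: assigned to the low group (deterministic).
- Tied event/censoring times: events first.
- Log-rank with zero variance: explicit error, not NaN.
- Zero-variance genes: dropped (z-score) or floored (signal-to-noise).
- ES magnitude ties: positive extremum preferred.
- Nominal permutation p: Laplace-corrected, floored at `1/(1 + n_perm)`.
- Duplicate gene ids on load: keep the highest-mean row (microarray
  collapse convention); missing-value rows dropped, never imputed.
- Time units: caller-declared, carried as metadata, never converted.

## Known limitations

Scores are cohort-relative, so absolute KD values are not portable across
datasets. The O/E hazard ratio is biased toward 1 relative to Cox under
heavy censoring imbalance. Gene-permutation GSEA understates inter-gene
correlation, making nominal p anti-conservative on strongly co-expressed
sets. `best_cutoff()`'s adjusted p corrects the scan's multiplicity but not
any upstream selection of which score to scan.
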