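Package: kdsig
Title: Knockdown Gene Signatures, Single-Sample Scoring and Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives up/down gene signatures from two-condition knockdown
    experiments by fold-change cutoff, computes per-sample knockdown (KD)
    scores as the difference of summed z-scores of up- versus down-regulated
    genes, stratifies patient cohorts by score or single-gene expression with
    native Kaplan-Meier estimation, log-rank testing and best-cutoff scanning,
    runs native preranked gene set enrichment analysis (weighted running-sum
    enrichment score, gene-permutation null, NES and nominal p), and provides
    the small bench-side calculations that accompany such studies (VIM/CDH1
    EMT classification, IHC H-score, delta-delta-Ct fold change, relative
    wound density). Includes synthetic discovery-experiment and
    expression-survival cohort generators with ground truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
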