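Package: pairsig
Title: Single-Sample Gene-Pair Prognostic Signatures for Censored Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates rank-based gene-pair prognostic signatures from
    expression cohorts with censored survival outcomes. Within each sample, gene pairs
    are reduced to binary indicators (1 when the first gene's expression exceeds the
    second's), a transform that is exactly invariant to any strictly increasing
    per-sample normalization and therefore robust to cross-platform batch effects.
    Candidate pairs are screened by univariate Cox regression, a sparse signature is
    fit by L1-penalized Cox regression with cross-validation, and a risk cutoff is
    chosen from the Kaplan-Meier based time-dependent ROC curve at a fixed horizon.
    Includes Kaplan-Meier/log-rank stratification, Cox covariate models, Harrell's
    concordance index with signature comparison, quartile and subgroup analyses,
    single-profile scoring, a permutation-based robustness assessment, and a seeded
    simulator of multi-batch survival transcriptomes with planted pair effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
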