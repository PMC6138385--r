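Package: prepvote
Title: Preprocessing-Ensemble Risk Classification for Prognostic Gene
    Signatures
Version: 0.1.0
Authors@R:
    person("prepvote", "developers", email = "prepvote@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how microarray preprocessing choices affect
    prognostic gene-signature risk stratification, and for combining many
    preprocessing pipeline variants into ensemble classifiers.  Implements
    median-dichotomized signature scoring with per-dataset or pooled
    stratification, unanimous-vote and random-forest ensemble classifiers
    over pipeline risk votes, engineered vote-summary features, Boruta
    all-relevant feature selection, survival-based evaluation (Kaplan-Meier,
    log-rank, unadjusted Cox hazard ratios, ROC/AUC), per-pipeline de novo
    signature discovery with FDR control, and a meta-ensemble over
    per-pipeline classifiers.  A synthetic-cohort generator with a latent
    hypoxia-activity factor, pipeline-specific monotone distortions and
    independent right-censoring makes the whole workflow testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
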