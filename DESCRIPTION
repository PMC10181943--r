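Package: icbscreen
Title: Expression Subtyping, Mutational Signatures and Biomarker Screening
    for Checkpoint-Blockade Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genomic and transcriptomic analysis of
    immune-checkpoint-blockade cohorts in non-small-cell lung cancer.
    Provides Bayesian non-negative matrix factorization with automatic
    relevance determination (ARD-NMF) as a shared engine for
    consensus-clustering-based expression subtyping (microenvironmental and
    tumor-intrinsic subtypes) and SBS96 mutational-signature extraction;
    per-sample genomic features (tumor mutational burden, clonality,
    neoantigen binder counts, receptor burden, metagene scores); a
    univariate logistic screen of features against best overall response
    with Benjamini-Hochberg tiers; Kaplan-Meier and log-rank survival
    stratification; and a synthetic-cohort generator that emulates the
    statistical structure these methods assume, so the full pipeline is
    testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
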