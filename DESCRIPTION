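Package: neofit
Title: Neoepitope Tumor-Fitness Scoring and Survival Prediction-Error
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring tumor neoepitopes against a database of viral
    epitopes and evaluating whether the resulting tumor-fitness measure
    predicts patient survival. Implements exhaustive Smith-Waterman peptide
    search with Karlin-Altschul e-values, the logistic TCR recognition
    potential, the MHC-I binding-affinity amplitude, and the maximal clonal
    immunogenicity score whose inverse is tumor fitness; cytolytic-activity
    (CYT) and tumor-mutation-burden (TMB) immune measures with
    Spearman association matrices; one-sided Kolmogorov-Smirnov comparison
    of neoepitope versus viral MHC-I binding-affinity distributions with
    subsampling robustness; entropy/length/support contig filtering and
    six-frame ORF extraction for viral antigen calling; Kaplan-Meier
    quantile-group analysis, Cox proportional-hazards models, and
    IPCW Brier-score prediction-error curves with integrated Brier scores
    under 0.632+ bootstrap resampling. A synthetic-cohort generator
    emulates the matched somatic-mutation, expression, and survival inputs
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
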