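Package: vmquant
Title: Quantification of Vasculogenic Mimicry and DSG2 Cohort Statistics
Version: 0.1.0
Authors@R:
    person("VMQuant", "Developers", email = "vmquant@example.org", role = c("aut", "cre"))
Description: Quantifies vasculogenic mimicry (VM) in two-channel PAS/CD31
    histology images using multiscale Hessian-based tubeness ridge detection,
    endothelial (CD31) network subtraction and tissue-area scoring, and
    implements the companion bulk RNA-seq cohort analysis: counts-per-million
    normalization, a keratinocyte-contamination sample filter on IVL/KRT14/BNC
    marker expression, DSG2 expression-range stratification, a negative-binomial
    exact differential-expression test, Kaplan-Meier / log-rank survival
    comparison and Fisher's exact test. Includes seeded synthetic-data
    generators (ground-truthed images and cohorts) used by the validation
    suite, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
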