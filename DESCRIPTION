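Package: methpair
Title: Patient-Matched Differential Methylome Analysis with a Three-State HMM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing genome-wide DNA-methylation profiles of
    patient-matched tumour pairs (for example intracranial versus extracranial
    melanoma metastases). Builds chromosome-ordered log2-ratio difference
    profiles per pair, quantifies local autocorrelation against a permutation
    null, classifies every CpG as decreased, unchanged or increased with a
    three-state Gaussian hidden Markov model trained by a maximum-a-posteriori
    (Bayesian) Baum-Welch algorithm, and provides the downstream analyses that
    such calls feed: hierarchical clustering with multiscale-bootstrap support
    values, one-sided Fisher enrichment of genomic annotation categories,
    majority-vote patient consensus and cross-patient candidate-gene ranking,
    alteration-burden summaries against clinical metadata, and gene-body
    methylation versus expression association. A synthetic-cohort simulator
    with ground-truth states makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    S4Vectors,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
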