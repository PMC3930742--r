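Package: acepred
Title: Lysine Acetylation Site Prediction from Peptide Sequence Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts N-epsilon lysine acetylation sites from protein
    sequence. Fixed-length peptide windows centered on candidate lysines
    are encoded with three sequence-derived features: mean amino-acid
    physicochemical properties from AAindex scales (AAPP), a first-order
    Markov transition log-likelihood ratio over adjacent residues (TPM),
    and a position-specific symbol composition score contrasting positive
    and negative positional residue frequencies weighted by positional
    information content (PSSC). Physicochemical scales are filtered by
    correlation-based feature-subset selection (CFS) with best-first
    search, and the features are integrated by a logistic regression
    classifier fitted by maximum likelihood. Includes greedy homology
    reduction of peptide windows, stratified k-fold cross-validation with
    repeated balanced negative resampling, a window-size scan, and a
    synthetic-data generator so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
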