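Package: orthokit
Title: Orthogroup Inference from All-vs-All Protein Similarity Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers orthogroups (sets of genes descended from a single gene in
    the last common ancestor of a set of species) from pre-computed all-vs-all
    protein BLAST results. Bit scores are normalised for gene length and
    between-species phylogenetic distance by per-species-pair log-log
    regression on the top-scoring hits of equal-count length bins; reciprocal
    best normalised hits delimit per-gene inclusion thresholds; the resulting
    weighted gene graph is partitioned by Markov clustering. Includes the
    evaluation metrics used for orthogroup benchmarks (pairwise
    precision/recall/F-score, length-binned accuracy, per-orthogroup error
    reports, random-deletion robustness), OrthoXML and plain-text writers, and
    a ground-truthed synthetic data generator based on gene duplication and
    loss along a species tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    Matrix,
    xml2,
    ape,
    ggplot2,
    generics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
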