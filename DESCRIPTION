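Package: nearaln
Title: Edge Reliability from Near-Optimal Protein Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring the near-optimal neighborhood of pairwise
    protein sequence alignments and scoring the reliability of individual
    aligned residue pairs (alignment edges). Implements semi-global and
    local affine-gap dynamic programming, Zuker-style per-edge constrained
    alignment scores and neighborhood sampling, per-edge robustness,
    frequency and maximum bits-per-position features, a logistic regression
    edge-reliability model with published default coefficients, alignment
    trimming and model-guided realignment, the Cline shift score for
    alignment-versus-alignment comparison, and a synthetic benchmark
    generator producing homologous sequence pairs with known true
    alignments and perturbed pseudo-structural references.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
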