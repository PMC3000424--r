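Package: peploc
Title: Subcellular Localization Prediction for Partial (EST-Derived) Peptides
Version: 0.1.0
Authors@R: person("peploc", "developers", email = "peploc@example.org",
    role = c("aut", "cre"))
Description: Predicts the subcellular localization of partial protein
    sequences such as those conceptually translated from expressed sequence
    tags (ESTs). Peptides are represented by 41 sequence-feature families
    (physicochemical AAindex summaries, k-th order amino-acid composition on
    the full and two reduced alphabets, and gapped pair composition), which
    feed radial-basis-function support vector machines trained and tuned
    under a nested 10-fold cross-validation protocol. Features can be
    integrated by attribute concatenation or by two-layer probability
    stacking. Scarce EST training data can be expanded by fragmenting
    full-length proteins into EST-like pieces followed by greedy identity
    clustering. A synthetic-data generator with plantable compositional and
    motif signal makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    truncnorm,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    quadprog,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
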