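Package: issnet
Title: Network-Based Prediction of Self-Harm Ideation Disclosure in Text Counseling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the transition point to disclosure of ideation about
    self-harm and suicide (ISS) in text-based counseling sessions. Builds a
    word affinity network from a conversation corpus (TF-IDF vocabulary,
    co-occurrence and CBOW-embedding-similarity edges), tests whether the
    words of a conversation block form a network module against a
    degree-matched random null, scores candidate blocks by their network
    separation (s-score) from known ISS blocks, and classifies pre-disclosure
    blocks with a trained sensitivity-plus-specificity-optimal threshold.
    Ships a lexicon-based ISS annotator with false-alarm filters and a
    synthetic corpus generator with planted prodromal-to-ISS lexical
    structure for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    data.table,
    Matrix,
    Rcpp,
    withr,
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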