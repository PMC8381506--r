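Package: repeatnet
Title: Nucleotide-Level Annotation of Genomic Repeats with a Recurrent
    Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates four classes of repetitive elements (HSAT2,3
    satellites, alphoid/alpha satellites, Alu elements and LINE-1
    retrotransposons) at nucleotide resolution in genomic DNA.  A
    shared-weight bidirectional gated recurrent network with additive
    attention scores sliding windows of the sequence and its reverse
    complement; per-position class probabilities are max-aggregated
    across overlapping windows, converted to signed logit scores, and
    segmented into classified BED intervals with a maximum-scoring-
    segments algorithm extended by a minimum-score threshold and an
    X-drop rule.  Includes training with class-balanced batches and
    early stopping, per-base evaluation (confusion matrices, FPR/FNR,
    multi-class Matthews correlation), a synthetic-genome simulator
    with planted repeats for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
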