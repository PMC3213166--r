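Package: siStack
Title: Two-Layer Stacked Regression for siRNA Efficacy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the silencing efficacy (percent inhibition of the
    target mRNA) of 19-nt siRNAs with a two-layer stacked ensemble.
    Layer one trains epsilon support-vector regressors on complementary
    representations of the sense strand: direct sequence encodings
    (numeric, one-hot binary, and a hybrid encoding that augments the
    one-hot code with per-position nucleotide/efficacy correlations),
    correlation-selected feature sets built from positional indicators,
    overlapping n-gram frequencies and nearest-neighbor duplex
    thermodynamics, and encodings of published siRNA design-rule sets.
    Layer two fuses the strongest layer-one predictors (one sequence
    method plus one feature method) through support-vector regression, a
    small 2-6-1 neural network, or a genetic-algorithm-evolved weighted
    sum, trained on out-of-fold layer-one predictions to avoid leakage.
    Candidate siRNAs scanned from a target mRNA are additionally
    stratified by whole-duplex stacking energy, which separates
    high-confidence from low-confidence predictions. Includes a
    synthetic-data generator with planted sequence and thermodynamic
    signal for end-to-end validation, an evaluation suite (Pearson r,
    accuracy, sensitivity, specificity, Matthews correlation
    coefficient), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    nnet,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
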