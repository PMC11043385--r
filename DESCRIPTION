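Package: leccdna
Title: Identification of Long Extrachromosomal Circular DNA from Sequence-Derived Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A predictive pipeline for long extrachromosomal circular DNA
    (leccDNA) identification. Transforms DNA sequences into thirteen
    statistical representations (k-mer composition, CKSNAP, PseEIIP,
    positional encodings, and pseudo nucleotide compositions), fuses feature
    vectors by concatenation, builds balanced benchmark-style datasets with
    dinucleotide-preserving shuffled negatives and redundancy filtering,
    locates information-rich sequence regions through subsequence 2-mer
    density-difference analysis, and benchmarks eleven machine-learning
    classifiers under 5-fold cross-validation and independent-test protocols
    with rank-score summaries. Includes a synthetic-sequence generator that
    plants a prefix-localized dinucleotide compositional signal so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    seqinr,
    e1071,
    MASS,
    class,
    rpart,
    randomForest,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
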