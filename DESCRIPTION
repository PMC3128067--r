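Package: oligoSeeds
Title: Evaluating Seed Quality for Oligonucleotide Design
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A framework for assessing how well contiguous, spaced,
    transition-constrained and multiple spaced seeds filter candidate
    oligonucleotides. Provides exact dynamic-programming and Monte-Carlo
    seed sensitivity under the Bernoulli alignment model, hash-based hit
    detection between a target sequence and its variants, a synthetic
    dataset generator that labels variants by identity, contiguous-match
    stretch and nearest-neighbour duplex free energy, precision, recall,
    F-score and efficiency evaluation with weight sweeps and bounded-recall
    rankings, and seed design by exhaustive search or overlap-complexity
    hill climbing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Biostrings, jsonlite, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Alignment, SequenceMatching, Software
RoxygenNote: 7.3.3
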