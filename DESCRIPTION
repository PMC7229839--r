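Package: ccra
Title: Calling Cards Reporter Arrays: Transposon-Based Measurement of
    Transcription-Factor Binding and Expression on Synthetic Promoter
    Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying transcription-factor (TF) binding from
    transposon calling-cards sequencing of barcoded synthetic promoter
    libraries in yeast, and for relating binding to reporter expression.
    Includes library and barcode design (single-bp motif landscapes,
    motif-spacing series, combinatorial site knockouts), demultiplexing and
    classification of paired-end reads, UMI-aware deduplication of insertion
    events, abundance-normalized binding scores (NBS), an EM Gaussian-uniform
    mixture model that separates TF-directed from background insertions,
    conversion of occupancies to binding free-energy differences, analysis of
    homotypic cooperativity against an additive two-site null including a
    helical-period cosine model and phase classification, Sort-Seq reporter
    expression estimation, PWM site scanning with summed-score regression,
    and a full simulator that generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
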