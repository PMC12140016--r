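Package: ttiri
Title: Two-Layer Transformer Identification of Transcriptional Infidelity Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcriptional-infidelity regions (RNA-DNA sequence
    differences) from DNA context with a two-layer transformer classifier:
    a byte-pair-encoding tokenizer over genomic sequence, an ALiBi-biased
    encoder, a CLS sequence-level head and a token-merging subregion-level
    head trained with a class-imbalance-weighted binary cross-entropy loss.
    Includes a synthetic-genome simulator with planted-motif benchmarks, and
    an interpretability stack quantifying position-specific hexamer,
    transcription-factor, and TF-family/class contributions via in-silico
    motif perturbation and position-weight-matrix scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
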