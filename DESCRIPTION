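Package: genedecoder
Title: Decoding Base-Wise Genic Probability Tracks into Eukaryotic Gene Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for base-wise labeling of eukaryotic genomes and for turning
    per-base genic-class and coding-phase probability tracks into structurally
    valid primary gene models in GFF3. Provides FASTA/GFF3 preprocessing with
    one-hot sequence encoding (including IUPAC ambiguity codes), annotation
    error masking and fixed-length subsequence windowing; a transition-weighted
    dual-head cross-entropy loss with a small trainable per-base classifier and
    sliding-window mean-ensemble inference; a penalty-minimising dynamic
    programming decoder over a splice-grammar state space with codon-phase
    tracking; base-wise and feature-level evaluation metrics; and a seeded
    synthetic genome generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
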