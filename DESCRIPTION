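Package: AnchorAlign
Title: Anchor-Based Divide-and-Conquer Multiple Alignment of Nucleotide
    Sequences
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multiple sequence alignment of long nucleotide sequences by
    k-tuple anchoring. A dictionary of all k-tuples (k = 1..M) is built in
    a single pass with exact counts, per-sequence counts and one-substitution
    inexact counts; k-tuples matched exactly once (allowing one substitution)
    in every sequence become seeds, which are resolved into an
    order-compatible anchor set via an incompatibility-distance matrix and
    iterative removal. Sequences are divided at the anchors and inter-anchor
    segments are aligned recursively or by a pluggable sub-aligner (a builtin
    progressive affine-gap profile aligner, or any external
    FASTA-in/FASTA-out tool), and the partial alignments are concatenated.
    Includes a sum-of-pairs identity scorer, a seeds-only rough-alignment
    mode for rapid triage of unalignable data, and a sequence-family
    simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
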