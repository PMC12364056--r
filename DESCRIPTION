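Package: cakl
Title: Commutative Algebra K-Mer Learning for Alignment-Free Sequence
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-free comparison of DNA/RNA sequences through
    persistent Stanley-Reisner invariants of one-dimensional
    Vietoris-Rips filtrations built on k-mer occurrence positions.
    Each k-mer's positions along a sequence form an integer point
    cloud; facet barcodes, persistent f- and h-vectors, and persistent
    graded Betti numbers of the induced filtration are assembled into
    fixed-length feature vectors, from which weighted algebraic
    distances between sequences are derived.  Downstream tools cover
    UPGMA tree inference with a monophyly purity score, leave-one-out
    1-NN and cross-validated k-NN classification on precomputed
    distances, and a synthetic sequence-family generator for
    end-to-end validation.  Brute-force simplicial oracles (GF(2)
    homology, Hochster subset-sums, maximal-subset facet enumeration)
    back every closed-form fast path with an independent check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
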