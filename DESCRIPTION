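Package: phlacross
Title: Electrostatic Surface Similarity of Peptide-HLA Complexes and TCR
    Cross-Reactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distance-based analysis of peptide-HLA (pHLA) surface similarity
    as a proxy for T-cell receptor cross-reactivity. Reads per-atom charge
    structures (PQR), aggregates them to per-residue feature tables under
    three structural scopes (whole complex, extracellular portion, epitope),
    decomposes rendered electrostatic-surface images into channel matrices
    and an informative-pixel composite, and computes Canberra (image space)
    and Euclidean (feature space) distances between epitopes. On top of the
    distance layer it identifies cross-reactive CDR3 sequences from
    TCR-epitope assay tables, correlates epitope-to-reference distances with
    T-cell activation readouts, and compares self, viral, and tumor epitope
    pools: shared-sequence census, pair-class distance statistics,
    closest-match mimicry classification, resampling shift, and
    Atchley-factor and amino-acid-class position statistics. A deterministic
    synthetic-data generator emulates the upstream docking, electrostatics,
    and rendering stages so every pipeline step is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    uwot,
    withr
Config/testthat/edition: 3
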