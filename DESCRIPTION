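Package: hotspotter
Title: Sequence-Based Prediction of Protein-Protein Interaction Hot Spots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hot spot residues in protein-protein interaction
    interfaces from sequence alone. Amino-acid physicochemical descriptors
    (AAindex1) are pruned by greedy correlation-threshold redundancy removal,
    each residue is encoded by a windowed auto-correlation of the descriptor
    profile along its chain (optionally with relative accessible surface
    area), and per-descriptor k-nearest-neighbour and RBF-kernel support
    vector machine base classifiers are ranked by cross-validated F1 and
    fused by majority voting over the top-n. Includes readers for
    alanine-scanning mutation tables, FASTA and NetSurfP output, a
    full evaluation toolkit (confusion-matrix metrics, ROC/AUC), a synthetic
    benchmark generator with planted auto-correlation signal, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    e1071,
    seqinr,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
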