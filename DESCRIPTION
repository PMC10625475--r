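Package: msecif
Title: Multi-Shelled and Distance-Weighted Interaction Features for
    Protein-Ligand Binding Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Distance-aware extensions of extended connectivity interaction
    features (ECIF) for protein-ligand binding affinity prediction.
    Implements the original single-threshold typed atom-pair counts, their
    multi-shelled (distance-binned) refinement, and inverse-distance-weighted
    pair sums, together with ligand descriptor assembly, gradient-boosted
    tree regression with the repeated-seed cross-validation protocol, and
    evaluation utilities (scoring power, enrichment factors, bootstrap and
    seed-ensemble model comparison, permutation feature importance,
    per-shell ablation). A synthetic fixture generator writes minimal
    PDB/SDF complexes with exactly specified atom types and distances so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ChemmineR,
    ChemmineOB,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
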