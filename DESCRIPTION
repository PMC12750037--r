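Package: caspr
Title: Assessment of Protein Structure Predictions with Composite Z-Score
    Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for CASP-style assessment of predicted protein monomer
    structures. Reads target and model coordinates from PDB or minimal
    mmCIF, extracts evaluation units (EUs), and computes the standard
    structure-comparison metrics: the GDT family under a seed-and-extend
    superposition search (validated against an exhaustive-subset oracle),
    GDC at ten distance thresholds, AL0_P, superposition-free lDDT,
    self-assessment agreement between submitted pLDDT and realized lDDT
    (ASE/QSE), and sidechain chi-angle accuracy (AAA). Rankings use the
    two-round z-score protocol with outlier exclusion and a -2 floor, a
    weighted nine-metric composite summed with per-EU weights, and
    head-to-head bootstrap significance. Cross-experiment progress is
    compared on difficulty-matched targets via Hungarian assignment and
    kernel-density weighted bootstrap resampling. A synthetic-data module
    builds toy targets, graded decoys with pLDDT, and latent skill-model
    score tables so the full pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
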