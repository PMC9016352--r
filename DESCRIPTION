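Package: hpslab
Title: Coarse-Grained Slab Simulations and Phase Analysis of TDP-43
    Low-Complexity Domain Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Residue-level coarse-grained modelling of liquid-liquid phase
    separation of the TDP-43 low-complexity domain and its phosphomimetic
    (S-to-D), control (S-to-A) and phosphoserine variants.  Implements the
    hydrophobicity-scale (HPS) force field with Ashbaugh-Hatch short-range
    interactions and Debye-Hueckel electrostatics, a Langevin dynamics engine
    with the slab coexistence protocol, density-profile and transfer
    free-energy analysis, residue contact maps and solvation histograms,
    Henderson-Hasselbalch net-charge calculations, and the quantification
    formulas used for sedimentation blots, FRAP traces and droplet
    morphology.  Deterministic synthetic-fixture generators make every
    analysis operator testable without cluster-scale simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    EBImage,
    bio3d,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
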