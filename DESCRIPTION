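Package: dockclass
Title: Docking-Score Classification Models for Ligand Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary activity classifiers from molecular docking scores.
    Implements kernel-density-intersection threshold classification, ensemble
    (multi-structure) rank-by-number score averaging, and Tanimoto-similarity
    weighted docking-score calibration with a cross-validated exponent grid
    search, together with the supporting metrics (Matthews correlation
    coefficient, balanced accuracy, ROC AUC, enrichment factor), a paired
    stereoisomer score comparison with interaction-fingerprint loss tallies,
    and a synthetic-data generator emulating gliflozin-like ligand libraries
    docked into multiple receptor conformations so the whole pipeline runs
    self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ChemmineR,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
SystemRequirements: OpenBabel (obabel on the PATH) for fingerprint generation
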