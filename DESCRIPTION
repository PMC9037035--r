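Package: dockscreen
Title: Hot-Spot Guided Virtual Screening Triage and Filter-Ensemble
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for triaging structure-based virtual screening output
    against a protein-protein interface. Identifies interface hot spots by
    frozen virtual alanine scanning with a declared simplified pairwise
    potential, profiles docked poses (geometric hydrogen bonds, attractive
    van der Waals contacts, Shrake-Rupley buried surface area), applies
    named interaction criteria with three-property Best/Worst labeling and
    ranking, computes an open set of 2D molecular descriptors, and trains
    an Iterative Stochastic Elimination (ISE) ensemble of descriptor-range
    filters scored by the Matthews correlation coefficient, with [-1, 1]
    index scoring, stratified cross-validation, enrichment curves and
    cutoff selection. Includes synthetic-data generators with ground-truth
    ledgers and a reproducible multi-stage pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
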