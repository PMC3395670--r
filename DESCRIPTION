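Package: cytocycle
Title: Cell-Cycle Expression Profiles from Asynchronous-Population Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts static multi-parameter cytometry measurements of an
    asynchronous, exponentially proliferating cell population into dynamic,
    same-scale cell-cycle expression profiles of cell-cycle regulated epitopes
    (cyclin A2, cyclin B1, phospho-S10-histone H3, DNA content). Provides a
    synthetic-population generator with known ground truth, event-table input
    and output (CSV and minimal FCS 3.1), spectral-overlap compensation and
    G1-anchored background subtraction, doublet and debris exclusion, region
    gating with Boolean algebra, automatic backbone-following segmentation of
    S phase and mitosis into ordered region chains, boundary-anchored
    constrained Gaussian deconvolution of the G1 and G2 clusters, DNA modal
    rescaling with equivalent S-phase gates for cross-assay same-scale
    correction, and piecewise-linear expression-versus-frequency and
    expression-versus-time profile synthesis using the exponential population
    age distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mgcv,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
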