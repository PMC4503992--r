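Package: cytomech
Title: Traction Force Microscopy, Microtubule Dynamics and Cohort
    Survival Analytics for Amoeboid Cell Mechanics
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@cytomech.dev",
           role = c("aut", "cre"))
Description: Quantitative pipeline for amoeboid cell mechanics studies:
    regularized Fourier-transform traction cytometry on elastic half-space
    substrates with cell-contour constrained inversion; per-cell traction
    read-outs (RMS traction, first-order moment matrix, net contractile
    moment, polarity ellipse); microtubule length-trace statistics
    (maximum length change, Mann-Whitney group comparison); gain-normalized
    3-D perinuclear shell intensity quantitation of confocal stacks;
    interactome fold-enrichment filtering; and expression-quartile
    dichotomization with Kaplan-Meier/log-rank survival comparison.  All
    stages are exercisable on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
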