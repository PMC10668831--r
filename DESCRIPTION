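Package: nichemax
Title: Optimal Maximum-Entropy Species Distribution Modelling with AICc Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-background ecological niche modelling built around a
    from-scratch L1-regularized maximum-entropy (MaxEnt) model with linear,
    quadratic, product, threshold and hinge features. Provides derivation of
    the 19 standard bioclimatic variables from monthly climatologies, grid
    thinning of occurrence records, contribution- and correlation-based
    variable screening, AICc-based calibration over a regularization-multiplier
    by feature-class candidate grid, subsample replication with AUC/TSS
    evaluation, jackknife variable importance, four-class suitability
    mapping with spherical cell areas, binary range-change overlays and
    centroid-migration vectors, plus a fully synthetic scenario generator
    with known niche truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
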