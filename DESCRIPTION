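Package: stentml
Title: Simulation-Driven Machine Learning for Stent Expansion in
    Calcified Coronary Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for predicting the post-stenting lumen
    area of calcified coronary artery cross sections from pre-stenting
    geometric features. Provides reduced-polynomial hyperelastic
    constitutive laws for arterial tissue, fibrotic plaque (with perfect
    plasticity) and calcification; a seeded generator of axially
    correlated labeled vessel cross sections; a composite-ring
    stent-expansion surrogate producing per-slice post-stenting lumen
    areas; extraction of the eight standard cross-sectional calcification
    and stretch features; and a regression stage comparing ordinary least
    squares with epsilon-insensitive support vector regression under
    linear, polynomial and radial basis function kernels, including the
    segment train/test protocol, feature-subgroup experiments,
    neighbor-averaged features, and percentage-error reporting with
    ANOVA/t-test group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
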