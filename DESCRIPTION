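Package: tricontinuum
Title: Three-Way Characterization of Continuous Tumor Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline that characterizes continuous transcriptional
    heterogeneity in bulk tumor cohorts from three complementary angles:
    archetype inference by fitting a minimum-volume enclosing simplex in PCA
    latent space (Pareto task inference), a k-topic grade-of-membership model
    fit by Poisson non-negative matrix factorization with per-gene topic
    posteriors, and cellular deconvolution against a labeled single-cell
    reference by repeated linear support vector regression with smoothing over
    a cell-state embedding. A synthetic-cohort generator produces
    ground-truthed convex-mixture data so every stage is validated by
    parameter recovery, and a consistency report aligns the three views.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
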