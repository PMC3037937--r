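Package: digeclass
Title: Differential Expression and Biomarker Panels for 2D-DIGE Proteomics
Version: 0.1.0
Authors@R: person("R.", "Meyer", email = "rmeyer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-dimensional difference gel
    electrophoresis (2D-DIGE) tissue proteomics with a pooled Cy2 internal
    standard: spot-volume normalization, spot-wise differential expression
    (Student t-test with a 1.5-fold filter), average-linkage clustering and
    single-feature partition classification with Fisher's exact test,
    outlier-robust principal component analysis with a projection/residual
    decomposition of each protein profile, a three-component logistic
    classifier evaluated by leave-one-out cross-validation, tumor-subgroup
    identification, and random protein-panel averaging experiments. Includes
    a synthetic-study generator that emulates a paired tumor/benign DIGE
    design with latent-factor class signal, so the whole pipeline is
    testable without access to raw gel images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
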