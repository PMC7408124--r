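Package: coumlox
Title: QSAR Modelling of Coumarin Lipoxygenase Inhibitors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a 37-compound set of 3-substituted coumarin
    (2H-chromen-2-one) lipoxygenase inhibitors from its substituent table,
    computes the 3D molecular descriptors of the published structure-activity
    model (Ghose-Crippen atom-centered fragment counts, polarizability-weighted
    radial distribution functions, and GETAWAY leverage autocorrelations),
    and provides the full small-data QSAR workflow around them: descriptor
    pre-filtering, cluster-based test-set selection, genetic-algorithm subset
    selection for multiple linear regression, leave-one-out and external
    validation statistics (Q2, Q2F1-F3, CCC, rm2, Y-scrambling), and the
    leverage-based applicability domain (Williams plot). A synthetic-data
    generator with known ground truth makes the selection and validation
    machinery testable without any molecule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
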