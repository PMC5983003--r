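Package: TessMut
Title: Tessellation-Based Four-Body Potentials and Computational Mutagenesis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Delaunay tessellation of C-alpha coarse-grained protein structures,
    derivation and application of the four-body knowledge-based statistical
    potential over residue quadruplets, and structure-based computational
    mutagenesis: residue environment (3D-1D) profiles, variant residual
    profiles and scores, and comprehensive mutational profiles. Includes
    construction of structure-derived variant feature vectors, cross-validated
    classification and regression of variant activity with permutation
    controls and learning curves, reporting utilities for structure-function
    summaries, and a synthetic-structure generator so the full pipeline can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    randomForest,
    e1071,
    rpart,
    nnet,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
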