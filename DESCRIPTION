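Package: cytoborder
Title: Observer-Independent Cytoarchitectonic Border Detection and Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for observer-independent cytoarchitectonic
    mapping of the cerebral cortex from cell-body-stained section images:
    gray level index (GLI) maps, Laplace-equation cortical traverses,
    depth-normalized laminar GLI profiles with 10-feature shape vectors,
    statistical detection of areal borders by sliding-window Mahalanobis
    distance with Hotelling's T-squared tests, multi-subject probability and
    maximum probability maps, shrinkage-corrected Cavalieri volumetry with
    mixed repeated-measures ANOVA, and hierarchical clustering of mean areal
    profiles. Includes a synthetic histology generator so every stage is
    testable without post-mortem material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    jsonlite,
    readr,
    EBImage,
    ape
Suggests:
    testthat (>= 3.0.0),
    MASS,
    tiff,
    png,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
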