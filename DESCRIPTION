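Package: pseudolesion
Title: Pseudo-Lesion Simulation and Modular Analysis of Functional
    Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the network consequences of focal brain
    lesions by comparing real-lesioned, pseudo-lesioned and hub-targeted
    functional connectomes. Implements background-connectivity estimation
    from residualized task time series, proportional thresholding and
    binarization, fixed-partition Newman modularity, participation
    coefficient and within-module degree z-score, mean-plus-one-SD hub
    identification, voxel-mask-to-node lesion resolution, PC/WD damage
    scoring, and permutation/bootstrap inference over lesion cohorts. A
    synthetic-cohort generator with planted modular and hub structure,
    contiguous left-hemisphere lesion masks and an optional re-organization
    transform allows the whole pipeline to run without neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    withr
Suggests:
    igraph,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
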