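Package: hdss
Title: High-Dimensional Symptom Space Models of Psychopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents each person-timepoint observation of an ordinal
    symptom questionnaire (119 items scored 0/1/2, CBCL-style) plus
    demographic covariates as a vector in a standardized feature space, and
    analyses the cohort through Euclidean distance geometry: pairwise
    distance matrices, average-person ("centroid") distances as a
    dynamically-normed severity index, within- versus between-category
    distances for DSM-proxy and HiTOP-style groupings, a common
    two-dimensional multidimensional-scaling embedding with a logistic
    clinical/non-clinical decision boundary, and longitudinal trajectories
    with boundary-crossing detection. Includes norm-referenced T-scoring
    against a reference sample, a seeded generator of CBCL-like longitudinal
    cohorts with known latent factor structure for validation, a full
    pipeline runner, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
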