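Package: idcpheno
Title: Image-Based Phenotyping and Genome-Wide Analysis of Soybean Iron
    Deficiency Chlorosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for scoring iron deficiency chlorosis
    (IDC) in soybean from top-down RGB canopy images and carrying the
    machine-derived phenotypes into quantitative genetics. Images are
    segmented in HSV space (saturation and hue thresholds, largest
    connected component), reduced to percent-yellow and percent-brown
    canopy features, and mapped to ordinal 1-5 IDC scores by a
    hierarchical linear support-vector-machine classifier and to a
    continuous 0-100 severity index by a fitted weighted combination.
    Downstream stages aggregate replicated plot records to line BLUPs,
    run a kinship-aware mixed linear model association scan with FDR
    control and LD clumping, classify two-locus allelic phase, and fit
    RR-BLUP genomic prediction with optional fixed covariates under
    k-fold cross-validation. Synthetic canopy-image and inbred-genotype
    generators with exact ground truth make every stage testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    grDevices,
    lme4,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
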