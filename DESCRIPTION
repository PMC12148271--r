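Package: lifespanSUD
Title: Lifespan Normative Modeling of Brain Volumetric Differences in
    Substance Use Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing grey-matter-volume trajectories between
    substance-use-disorder and healthy-control groups across the lifespan.
    Implements scanner harmonization, generalized-gamma normative models with
    fractional-polynomial age bases selected by BIC, centile scoring, fine
    age-grid divergence testing with false-discovery-rate control, behavioral
    common-factor extraction and brain-behavior correlation, spin-permutation
    association of brain maps with cognitive-term atlases, and a genetics arm
    (genotype QC, association testing, a weighted grey-matter-volume score,
    LD pruning, polygenic scoring and conditional/conjunctional FDR). A
    synthetic multi-cohort data generator with a ground-truth manifest makes
    every stage testable without protected cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    S4Vectors,
    SummarizedExperiment,
    sva,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
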