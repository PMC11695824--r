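Package: mcedfusion
Title: Hotspot ctDNA Mutation Calling and Fusion with a Multimodal
    Cancer Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Amplicon-panel hotspot mutation calling from plasma
    cell-free DNA allele counts: per-site baseline variant-allele-fraction
    (VAF) cutoffs calibrated on negative-control plasmas, assay limit of
    detection estimated from titrated reference standards, amplicon
    coverage QC, clonal-hematopoiesis (CHIP) filtering against matched
    white-blood-cell counts, and sample-level ctDNA positivity. Hotspot
    calls are fused with a multimodal cancer-probability score under an
    OR rule; the evaluation layer reports per-cancer-type and per-stage
    sensitivity and specificity with Wilson score intervals, concordance
    quadrants, gene-level mutation prevalence and recurrent-site
    summaries. A synthetic-cohort generator with a ground-truth channel
    reproduces the statistical structure the pipeline assumes, so every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
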