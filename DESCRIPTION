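Package: cnaprog
Title: Copy-Number Alteration Progression Analysis for Sequential Premalignant Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for array-CGH copy-number analysis of
    sequential premalignant lesions and same-site carcinomas: change-point
    segmentation of probe-level log2-ratio profiles, gain/loss calling against
    linear-ratio thresholds, population CNV filtering by reciprocal overlap,
    subtraction of alterations seen in non-progressive controls,
    sequential-recurrence classification across graded lesion series,
    hierarchical clustering of copy-number profiles, and the validation-arm
    statistics (delta-delta-Ct relative quantification, Kruskal-Wallis and
    Fisher's exact tests). Includes a seeded synthetic-cohort generator with
    implanted truth sets for every downstream component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse,
    jsonlite
Config/testthat/edition: 3
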