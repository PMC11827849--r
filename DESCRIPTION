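Package: titinreg
Title: Quantitative Analysis of Titin Enhancer Activity, Allele-Specific
    Expression, and Cardiomyocyte Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for the quantitative assays used to
    characterize cardiac enhancer elements in the titin (TTN) locus.
    Implements massively parallel reporter assay (MPRA) quantification
    with counts-per-million normalization, quality-control exclusions,
    per-position mutagenesis effect maps and construct-versus-wild-type
    testing; allele-specific expression estimation from
    strain-distinguishing SNP counts with cis/trans testing, qPCR
    delta-delta-Ct quantification and Mendelian-ratio tests; two-stage
    subpixel micropillar deflection tracking with conversion to twitch
    force and stress; sarcomere filament segmentation and metrology
    (axis lengths, spacing, orientation) with flow-cytometry MEFL bead
    calibration; and the shared statistical primitives (Welch t,
    chi-square goodness of fit, exact binomial enrichment,
    Benjamini-Hochberg adjustment). Seeded synthetic-data generators
    emulate each assay with ground-truth records for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
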