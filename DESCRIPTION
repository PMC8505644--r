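Package: hpameth
Title: Candidate-Gene DNA Methylation Analysis of HPA-Axis Dysregulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for candidate-gene DNA methylation analysis
    of hypothalamic-pituitary-adrenal (HPA) axis dysregulation. Selects CpG
    probes within a window of the transcription start site for a panel of
    HPA-axis genes (CRH, CRHBP, CRHR1, CRHR2, FKBP5, NR3C1), fits per-probe
    linear models on the M-value scale with empirical-Bayes variance
    moderation and FDR control, tests each gene transcript for an abundance
    of nominally significant CpG sites with exact binomial tests under
    Bonferroni correction, and correlates methylation with gene expression
    in independent cohorts using Pearson and MM-type robust regression.
    Includes a synthetic-cohort generator that reproduces the statistical
    structure of a dexamethasone-suppression-test case/control study for
    calibration and parameter-recovery testing, plus Table-1-style group
    comparisons, forward covariate selection, PCA-based sample QC, and
    interaction post-hoc models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
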