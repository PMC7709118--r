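Package: crossmark
Title: Cross-Platform Quantitation and Harmonisation of Plasma Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies a three-protein plasma biomarker panel (APOA4, CD5L,
    IGFBP3) from immunoaffinity mass-spectrometry (MRM) transition reports and
    from sandwich-ELISA plate readings, validates both assays (linearity,
    LOD/LOQ, precision, stability against FDA ligand-binding criteria), gates
    batches with a rolling mean +/- 2 SD reference-plasma rule, harmonises the
    two platforms by Bland-Altman bias estimation and adjustment, and assesses
    concordance of a composite diabetic kidney disease risk score. Includes a
    synthetic-data module that emulates a paired 100-subject plasma cohort with
    known ground truth so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
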