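Package: stainscore
Title: Automated Scoring and Evaluation of Paper-Based Sickle Cell Screening Stains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative scoring of the paper-based sickle cell
    screening test. Dried blood stains on chromatography paper are detected in
    scanned sheets, their red color intensity (255 minus the Blue channel) is
    profiled radially, and two densitometric indices are computed: the S-index
    (center-spot to peripheral-ring mean intensity ratio, a proxy for the
    sickle hemoglobin fraction) and the C-index (total center intensity times
    mean intensity at 5 mm, a proxy combining HbS amount and total hemoglobin).
    Indices are turned into HbAA/HbAS/HbSS genotype calls and calibrated to
    percent HbS. A full diagnostic-performance stack (confusion matrices,
    sensitivity/specificity/PPV/NPV/accuracy with Wilson score intervals,
    ROC/AUC, Fleiss' kappa, per-rater summaries) and a synthetic stain
    generator with known ground truth make every stage testable end to end
    without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
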