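Package: diamus
Title: Area-Method Quantification of Hemidiaphragm Movement from Ultrasound Cine Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cranio-caudal hemidiaphragm movement from B-mode
    ultrasound cine loops with the Area method (change in supradiaphragmatic
    "intra-thoracic" area between maximal and minimal diaphragm contraction,
    obtained by closing the traced diaphragm contour with the fixed image
    borders), together with the two established comparators: M-mode excursion
    along a scan line and B-mode apex displacement. Includes a synthetic
    diaphragm-dome phantom with speckled B-mode-like rendering and analytic
    ground truth, a cohort simulator for method-validation studies, and the
    accompanying statistical battery (Spearman rank correlation with Fisher-z
    confidence intervals, mean-split subgroup correlations, one-way intraclass
    correlation, and exact Clopper-Pearson binomial intervals).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    tiff,
    png,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
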