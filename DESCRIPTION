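Package: cacscore
Title: Coronary Artery Calcium Scoring on Contrast-Enhanced CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of coronary artery calcium (CAC) from
    contrast-enhanced coronary CT angiography (CCTA), validated against the
    clinically standard Agatston and volume scores from dedicated calcium
    scoring CT (CSCT). Provides the reference per-slice Agatston scorer, a
    classical CCTA segmentation stack (Gaussian-mixture intensity modelling,
    Hessian vesselness, ascending-aorta detection and an aorta-derived
    calibration factor), centerline extraction by 3D thinning, an adaptive
    HU-threshold calcium extractor with calibration-scaled Agatston weights,
    method-agreement statistics (Lin's concordance, Bland-Altman, linear
    weighted kappa, five-category risk reclassification), and a synthetic
    paired CSCT/CCTA cardiac phantom generator with known ground truth so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
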