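Package: pibquant
Title: Noninvasive Quantification of Dynamic PiB PET with an Image-Derived
    Input Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies dynamic [11C]PiB amyloid PET studies without arterial
    blood sampling: extraction of an image-derived input function (IDIF) from
    internal-carotid voxels, Hill-type metabolite correction to a plasma input,
    voxel-wise Logan graphical analysis yielding distribution-volume (DV) and
    DVR images, reference-tissue Logan DVR, SUV/SUVR from a late static window,
    and the regional, agreement (Pearson regression, Bland-Altman with a
    Pitman-Morgan variance comparison) and ROC/Youden statistics used to
    compare the three metrics.  A synthetic dynamic-PET brain phantom with
    two-tissue-compartment kinetics and a parametric arterial input provides
    known-answer data so that every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
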