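Package: cermetrics
Title: Corneal Exposure Ratio Measurement from Eye Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the corneal exposure ratio (CER) from frontal eye
    photographs or precomputed segmentation masks, for quantifying ptosis
    (drooping eyelid) surgery outcomes. The pipeline localizes the pupil and
    iris with a Hough circle transform on segmentation-mask boundaries,
    reconstructs the full limbal disc as a Boolean mask, intersects it with
    the exposed-eye (palpebral fissure) mask, and reports the exposed
    fraction as a percentage, optionally calibrated to millimetres via the
    interlimbal distance. Includes a parametric synthetic eye generator with
    analytically known ground truth, and the method-agreement statistics used
    to validate automated ocular biometry: intraclass correlation
    coefficients with confidence intervals, Bland-Altman bias and limits of
    agreement, paired t-tests, one- and two-way ANOVA, severity
    stratification and pre/post improvement rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    graphics,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
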