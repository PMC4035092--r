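Package: wmquant
Title: Quantitative Image Analysis of White-Matter Myelin Pathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying early white-matter pathology on light,
    confocal and electron micrographs: detection of hyperintense myelin-debris
    foci by topographic prominence of regional local maxima, oligodendrocyte
    counting via DAPI nucleus segmentation and marker-positivity ratios,
    microglial stained-area fractions by Otsu thresholding, object-based
    axon/debris colocalization from perpendicular line profiles, g-ratio
    quantification, and electron-microscopy lesion-census statistics with
    unbiased counting frames and an eccentric-sectioning (sphere-profile)
    diameter correction. A synthetic-micrograph generator with known ground
    truth makes every estimator verifiable end to end, and group comparisons
    are reported as mean +/- SEM with Student's t tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
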