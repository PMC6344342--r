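Package: steatoquant
Title: Lipid Droplet Detection and Steatosis Quantification in Liver
    Histology
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects circular lipid vacuoles in hematoxylin-and-eosin
    stained liver sections with a circular Hough transform, reports
    per-droplet diameter and area in physical units, builds
    size-distribution histograms, and compares group distributions with
    the Cochran-Armitage chi-square test for trend.  Also quantifies
    positively stained area fractions (e.g. Picrosirius red collagen
    staining) and ships a synthetic-histology generator with ground-truth
    circle records so the whole pipeline is testable without slides.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
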