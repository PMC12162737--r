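Package: radiomap
Title: Parametric Radiomic Feature Maps and Field-of-View Reproducibility
    for Cardiac Cine MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates short-axis cardiac cine slices at multiple fields of
    view, extracts a 93-feature radiomic signature (first-order, GLCM, GLDM,
    GLRLM, GLSZM and NGTDM classes) both conventionally from a region of
    interest and through tile-based parametric feature maps, and quantifies
    feature reproducibility across fields of view with coefficients of
    variation at a 10% stability cutoff. Includes a synthetic left-ventricle
    phantom with spatially correlated myocardial texture, threshold-based
    myocardium segmentation, NRRD input/output, and tidy reporting and
    plotting of stability comparisons between the two extraction strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
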