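Package: rtpvr
Title: Real-Time MRI Pressure-Volume Analysis of the Left Ventricle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving left-ventricular end-systolic pressure-area
    (ESPAR) and pressure-volume (ESPVR) relationships from 2D real-time
    short-axis MRI acquired during preload reduction (vena cava occlusion).
    Includes a synthetic phantom generator with known ground truth,
    frame-propagated level-set segmentation of the LV cavity with a shape
    prior, moment-based ellipse shape descriptors with cavity-obliteration
    handling, pressure filtering, calibration and image synchronization,
    iterative maximal-elastance end-systole detection, trapezoidal ESPVR
    reconstruction, and conductance-catheter calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    purrr,
    tibble,
    tidyr,
    ggplot2,
    rlang,
    generics,
    stats,
    signal,
    pracma,
    tiff,
    RNifti,
    EBImage,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
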