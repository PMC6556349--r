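Package: laa3d
Title: Morphological and Functional Assessment of the Left Atrial Appendage from Multi-Phase Cardiac CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface-based three-dimensional analysis of the left atrial
    appendage (LAA) across the cardiac cycle. Provides threshold-based
    blood-pool segmentation of contrast-enhanced CT volumes, watertight
    isosurface extraction, plane-based cropping of the appendage submesh,
    ostium cutting-plane definition from landmarks, ostium contour and area
    measurement, surface capping and voxelization-based volumetry, the
    classical slice-stack Simpson volume as a two-dimensional reference,
    phase-resolved volume-time curves with automatic diastole/systole
    detection and ejection fraction, body-surface-area normalization, and
    method-agreement statistics (within-subject coefficient of variation,
    Bland-Altman limits of agreement, paired t-test). A dynamic digital
    phantom with analytic ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
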