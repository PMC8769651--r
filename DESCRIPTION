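Package: fibclem
Title: Automated Cryo-FIB Milling and 3D Correlative Light-Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for automated cryo-focused-ion-beam (cryo-FIB)
    lamella preparation guided by three-dimensional correlative light and electron
    microscopy (3D-CLEM). Implements fiducial bead detection and subpixel Gaussian
    localization, fitting of 3D-fluorescence-to-2D-SEM/FIB correlation transforms,
    beam-geometry prediction of fiducial positions in the ion-beam view, lamella
    volume masks and masked maximum-intensity "virtual slice" projections, robust
    3D affine registration between fluorescence and FIB-SEM volumes (RANSAC,
    multi-start and basin-hopping strategies), FIB-SEM slice-stack postprocessing
    (wavelet de-curtaining, charging compensation, CLAHE, subpixel drift
    alignment, foreshortening correction), a milling protocol and pattern-sequence
    compiler with dose and session accounting, and a simulated microscope driver
    with a voxelized virtual specimen for end-to-end testing of automated milling
    sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    tiff,
    minpack.lm,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
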