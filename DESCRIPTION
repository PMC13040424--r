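Package: cervimorph
Title: Automated Cervical Biometry and Volumetry from 3D MRI Label Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the late-gestation cervical biometry panel (2- and
    3-point cervical length, internal and external os diameters,
    utero-cervical angle, compartment volumes) from 3D multi-label
    segmentations of the uterocervix stored as NIfTI label volumes. A
    canal centerline is extracted as a distance-penalized geodesic through
    the cervical canal, os landmarks are located at its ends, and all
    geometry is measured in world (mm) space. Includes an analytic phantom
    generator with closed-form ground truth for validation, a synthetic
    cohort simulator, and the accompanying statistical battery: Shapiro-Wilk
    normality testing, 1.5 x IQR outlier filtering, two-way random-effects
    intraclass correlation, and linear/logistic generalised linear models
    relating cervical measurements to demographics and birth outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
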