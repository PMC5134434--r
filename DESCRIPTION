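Package: mangovision
Title: Machine-Vision Shape Classification and Mass Grading of Mango Fruit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Grades mango fruit from a single two-view image (top view plus a
    mirror-reflected side view) the way an in-line optical sorter does.
    Segments the fruit silhouette in each view by multi-pass global
    thresholding on the blue and green channels, calibrates pixel
    measurements to millimetres with a pinhole scale model recalibrated per
    image from the fruit height, computes size-shape parameters and
    Fourier-descriptor shape features from the boundary distance signature,
    classifies regular versus misshapen fruit with Fisher linear
    classification functions (with stepwise Wilks' Lambda feature
    selection for retraining), estimates volume from the two orthogonal
    silhouettes by the disk method and mass by linear regression on volume,
    and assigns commercial grades. Includes a synthetic two-view scene
    generator with known ground truth, and the paired t-test / Bland-Altman
    agreement statistics used to validate the measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
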