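Package: patellometry
Title: Automatic Patellofemoral Segmentation and Measurement on Knee CT Slice Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic measurement of patellar dislocation on ordered
    stacks of knee computed-tomography slices. Implements local nonlinear
    contrast enhancement, inter-slice bone-region prediction (selective
    revert, fusion with the previous segmentation, sutura weakening and
    separating-layer clearing), two-phase Chan-Vese level-set segmentation
    of femur and patella, key-point based least-squares central-plane
    fitting, and the derived clinical quantities: patellar tilt angle (PTA,
    degrees) and patellar lateral shift (PLS, millimetres) with a rule-based
    diagnosis. Ships a synthetic knee phantom generator with analytically
    known ground truth and the standard segmentation quality metrics
    (overlap rate, false-positive rate, Dice coefficient, separation rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
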