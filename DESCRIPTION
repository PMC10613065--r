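Package: grainscan
Title: Backlight Image Analysis for Rice Grain Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Measures rice grain phenotypes from backlight (transmitted
    light) images. Restores distorted line-scan turntable captures by a
    log-polar remapping, segments individual grains with marker-based
    watershed flooding, classifies each grain as filled or unfilled from
    the dark ratio of a two-cluster grayscale partition, and measures
    grain length and width in millimeters via the minimum-area enclosing
    rectangle. Includes a synthetic backlight scene generator with full
    ground truth, the evaluation statistics (coefficient of
    determination, RMSE, MAPE) and a dark-ratio threshold sweep for
    assessing counting accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
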