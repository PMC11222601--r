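Package: dsacolor
Title: Color-Coded Parametric Imaging for Digital Subtraction Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Per-pixel bolus-model time-intensity curve fitting for 2D+time
    digital subtraction angiography (DSA) sequences, derivation of five
    perfusion parameter maps (area under the curve, time to peak, time of
    arrival, transit time and contrast inflow rate), and pseudo-color
    rendering that highlights active bleeding as late, persistent contrast
    arrival. Includes a synthetic angiography phantom (tube plus optional
    extravasation blob with ground-truth arrival times) for validation,
    a paired Likert reader-score module with an exact/approximate Wilcoxon
    signed-rank test, and a command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
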