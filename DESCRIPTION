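Package: pdprobe
Title: Finite-Difference Partial-Derivative Saliency Probing for
    Black-Box Image Regressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probes any black-box image-to-scalar regression model (for
    example a bone-age estimator reading hand radiographs) by
    finite-difference partial-derivative saliency mapping.  Provides the
    radiograph preparation chain (background subtraction, binary hand
    masking with morphological island removal, square crop, resize, 2x2
    cell packing into a 3-channel 299x299 image, 0-254 intensity
    scaling), the per-pixel +1 intensity probe, region-of-interest
    quantification of absolute partial derivatives, trend regression of
    relative mean absolute partial derivatives against reference age,
    and sigmoid-compressed diverging color overlays.  Ships closed-form
    surrogate regressors and a seeded synthetic hand-phantom generator
    so every stage is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
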