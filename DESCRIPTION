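Package: slogait
Title: Foot-Ground Contact Phase Classification with Sliding-Window Label
    Overlapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for real-time foot-ground contact phase classification
    from wearable motion-sensor time series. Provides a seeded synthetic gait
    generator, force-sensitive-resistor (FSR) based sub-phase labeling,
    noise augmentation and z-score standardization, sliding-window label
    overlapping (SLO) dataset construction with grayscale window-image
    encoding, a small convolutional neural network classifier trained with
    adaptive moment estimation, and Taguchi L9 orthogonal-array level-average
    analysis of the SLO ratio and convolution filter size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
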