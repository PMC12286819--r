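Package: vfprompt
Title: Glottis-Driven Prompt Engineering for Vocal-Fold Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds box and point prompts for promptable segmentation
    backends from low-threshold glottis probability masks in laryngeal
    high-speed videoendoscopy. Includes CLAHE-based mask fusion, pose
    normalization, morphological contour selection, derivative-extrema
    boundary-point extraction, an iterative prompting driver with a
    pluggable backend contract, mask-derived clinical waveforms (glottal
    area, vocal-fold movement and width), Dice evaluation, and a synthetic
    laryngoscope phantom with analytic ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
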