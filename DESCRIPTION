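Package: huecat
Title: Emergent Color Category Analysis for Learned Visual Representations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting emergent color categories in a learned
    visual representation. Implements probe-head (readout) training over
    shifting hue bands on the circular HSV hue spectrum, border-transition
    analytics (transition counts, Gaussian smoothing, circular peak
    detection, reciprocal-weighted category prototypes, circular
    cross-correlation shift analysis, Fisher comparison, histogram
    overlap), an evolutionary border search whose fitness is the learning
    speed of a readout, within-category and colored-object generalization
    experiments, and match-to-sample psychophysics statistics with a
    bootstrap null. Ships synthetic stimulus generators (colored-word
    rasters, multi-word distractor scenes, enclosure-filled outline
    shapes) and simulated categorical/continuous responders so every
    analysis runs end-to-end from a seed with no downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
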