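Package: glycoprobe
Title: Quantitative Analysis of Fluorogenic Glycan-Probe Imaging Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for characterizing a fluorogenic, red-shifting
    glycan-binding dye: two-state photophysics and turn-on contrast,
    pseudo-first-order binding kinetics (kobs regression yielding kon, koff
    and KD), hyperspectral excitation-scan peak mapping, FLIM phasor
    population gating, glycan-microarray spot quantification with
    Dunnett-corrected statistics, and photostability metrics. A synthetic
    data generator with recorded ground truth feeds every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr
Config/testthat/edition: 3
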