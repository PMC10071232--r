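Package: chromadoe
Title: Factorial Development and Validation of Chromatographic Assays
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: A desk-scale workbench for reversed-phase liquid-chromatography
    method development and validation. Simulates chromatograms from
    exponentially-modified-Gaussian ground truth, measures system-suitability
    statistics (capacity factor, resolution, tailing factor, theoretical
    plates), estimates two-level full-factorial effects with Lenth
    significance and natural-unit prediction equations, optimizes factor
    settings by Derringer desirability, computes calibration statistics with
    sigma/slope and signal-to-noise detection limits, quantifies samples by
    classic and instrumental standard addition, estimates standard-solution
    storage periods from calibration-slope drift, and scores analytical
    greenness (Eco-scale and AGREE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
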