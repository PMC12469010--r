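Package: swtflda
Title: Stationary Wavelet Sub-Band Features and Fisher Discriminant
    Classification for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Undecimated (stationary) wavelet decomposition of multi-channel
    EEG with the Daubechies-4 filter bank, hard/soft wavelet-shrinkage
    denoising with level-dependent universal thresholds, sub-band feature
    extraction in the theta/beta/gamma rhythms, and Fisher Linear
    Discriminant projection with an equal-prior linear decision rule.
    Includes subject-wise stratified train/test evaluation with
    confusion-matrix metrics and a seeded synthetic two-class EEG cohort
    generator with planted band-specific class effects for end-to-end
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
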