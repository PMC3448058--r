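Package: acetox
Title: Acetic Acid Toxicity Analysis for Multifactorial Yeast Plate Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies acetic-acid toxicity in batch yeast cultures from
    multifactorial plate-reader experiments. Provides space-filling (maximin)
    experimental designs over glucose, pH and acetic-acid axes with linear or
    logarithmic scaling; sliding-window estimation of the specific growth rate
    from log-OD time series; Gaussian-process (Kriging) response-surface models
    with generalized cross-validation noise estimation and Nelder-Mead
    length-scale optimization; dose-response slices along the acetic-acid axis
    with EC50, toxicity integrals and relative-viability statistics; two-point
    oxygen-sensor and ratiometric pHluorin calibrations; and a mechanistic
    synthetic plate simulator (Monod growth with Henderson-Hasselbalch weak-acid
    inhibition) for validation and demonstration without robot-generated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
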