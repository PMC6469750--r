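Package: elisashift
Title: Batch-Effect Correction for ELISA Standard Curves via Shift Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects lot-to-lot (batch) variability in ELISA quantification.
    A best-fit reference standard curve is modelled with a four- or
    five-parameter logistic function, a per-batch shift factor S on the
    log-concentration axis is estimated by nonlinear least squares, and
    unknown-sample concentrations are adjusted onto a uniform platform.
    Includes inverse prediction with range flagging, longitudinal
    quality-control reporting (inter-assay CV, shift-factor outlier
    detection), a synthetic plate generator with known truth for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
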