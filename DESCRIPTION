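Package: aerofit
Title: Modelling the Longitudinal Pattern of Aerenchyma Formation in Rice Roots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits sigmoid growth models (W0-Gompertz, Ti-Gompertz, logistic,
    von Bertalanffy) to profiles of aerenchyma percentage measured along rice
    adventitious roots, compares them by R-squared, AIC and BIC, and diagnoses
    parameter bias by residual bootstrap. From the selected Ti-Gompertz form
    it extracts the biologically meaningful critical points (initial point,
    maximum acceleration, inflection, maximum deceleration, 95% of maximum),
    decomposes formation into five stages with per-stage rates, unifies the
    parameters as piecewise-linear functions of root length, and integrates
    the fitted curve to estimate whole-root aerenchyma volume. A synthetic
    profile generator reproducing the study design (0.5-cm sectioning,
    replicated measurements, detection floor, basal exclusion) makes the full
    pipeline testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
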