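Package: iolconst
Title: Formula Constant Optimization for Intraocular Lens Power Calculation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing intraocular lens (IOL) power formula
    constants against postoperative refractive outcomes. Implements the
    SRK/T, Hoffer Q, Holladay 1, and simplified Haigis formulae (refraction
    prediction and IOL power calculation), refraction prediction-error
    metrics (mean, standard deviation, and root-mean-square prediction
    error), six constant-optimization strategies including joint
    constant/refractive-offset and constant/keratometer-index optimization
    and the sequential two-step procedure (minimize the standard deviation
    of the prediction error with the formula constant, then zero the mean
    with a refractive offset), and a synthetic pseudophakic cohort
    generator for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
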