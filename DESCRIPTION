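Package: insukin
Title: Insulin Kinetics Modelling with Amino-Acid Effects During Mixed-Meal
    Tolerance Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compartmental models of plasma insulin kinetics during a
    mixed-meal tolerance test (MMTT), in which plasma glucose and amino-acid
    (AA) concentrations act as known forcing inputs. Provides five candidate
    ordinary-differential-equation models with steady-state basal closures,
    multistart bound-constrained nonlinear least-squares estimation with
    asymptotic uncertainty quantification (CV%, 95% confidence intervals),
    small-sample Akaike model comparison (AICc and relative likelihoods),
    constrained virtual-population generation from mean +/- SD template
    curves, a synthetic MMTT curve generator with known ground-truth
    parameters, and downstream population statistics (beta-cell amino-acid
    sensitivity sign classification, correlation, regression and group
    tests). Includes a command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
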