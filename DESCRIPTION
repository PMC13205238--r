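Package: asltk
Title: Accelerated Shelf-Life Testing Kinetics for Nutrient Degradation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits zero-order, first-order, and Weibull primary kinetic
    models to isothermal nutrient degradation data, models the temperature
    dependence of the Weibull scale parameter with Arrhenius and
    log-logistic secondary models, computes retention-threshold shelf life
    (t80) from fitted Weibull parameters, and extrapolates shelf life to
    unmeasured storage temperatures via an Arrhenius regression on t80.
    Includes analytical utilities (titratable acidity, external-standard
    HPLC calibration with LOD/LOQ, Pearson correlation screening), a
    synthetic degradation-study generator that reproduces the statistical
    structure of multi-temperature accelerated storage designs, a
    parameter-recovery harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
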