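Package: movecoda
Title: Compositional Data Analysis of 24-Hour Movement Behaviours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing daily time-use compositions (sleep, sedentary
    time, light and moderate-to-vigorous physical activity) under Aitchison
    geometry. Provides closure and isometric log-ratio (ilr) transformations
    with user-selectable sequential binary partitions, compositional means and
    pairwise log-ratio variation matrices, linear models of health outcomes on
    ilr coordinates with sociodemographic covariates (including Type II
    marginality tests and regression diagnostics), and compositional
    isotemporal substitution: predicted outcome differences when fixed
    durations of time are reallocated between behaviours around arbitrary
    baseline compositions. Includes a calibrated logistic-normal synthetic
    data generator for testing and parameter-recovery experiments, delimited
    text and spreadsheet readers, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    readxl,
    withr
Config/testthat/edition: 3
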