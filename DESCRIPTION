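Package: thermaldev
Title: Temperature-Dependent Development Rate Models and Degree-Day Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing insect thermal performance from life-table
    experiments run at constant temperatures. Fits the classical linear
    degree-day model and the Briere nonlinear development-rate curve to
    egg-to-adult development rates, derives lower and upper developmental
    thresholds, degree-day requirements and the optimum temperature, and
    predicts adult emergence by degree-day accumulation over daily mean
    temperature series. Includes a seeded life-table simulator that emulates
    a constant-temperature rearing design (two pupal parasitoid species, two
    sexes, five temperatures) for parameter-recovery validation, plus a small
    command-line interface for fitting, phenology prediction and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
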