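Package: scsolub
Title: Machine-Learning and Density-Based Modelling of Drug Solubility in Supercritical CO2
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models mole-fraction solubility of a solid drug in supercritical
    carbon dioxide as a function of pressure and temperature. Provides
    from-scratch Gaussian process regression with a squared-exponential
    kernel and maximum-likelihood hyperparameters, kernel ridge regression,
    and a CART-style regression tree; density-based semi-empirical
    correlations (Kumar-Johnston, Bartle) fitted by AARD minimisation over a
    Peng-Robinson equation-of-state density backend; evaluation metrics,
    grid-search tuning, response-surface and optimum analysis, crossover
    pressure location, and a synthetic-data generator for parameter-recovery
    studies. Ships a 32-point decitabine/SC-CO2 solubility dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
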