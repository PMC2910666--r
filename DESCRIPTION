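Package: conjointgrowth
Title: Conjoint Tumor-Normal Cell Growth Dynamics Under Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator for the conjoint growth of a normal
    (aging fibroblast-like) cell population and a tumor cell population
    coupled through bidirectional interaction terms with a critical tumor
    size, under static or exponentially decaying chemotherapy with a
    saturating fractional-cell-kill response. Tumor growth follows a
    generalized-logistic (Richards) law spanning the logistic and Gompertz
    limits. Provides closed-form growth oracles, an adaptive piecewise ODE
    engine with event extraction (threshold crossings, population peaks,
    inhibition-onset delays, trajectory distances), a registry of named
    scenario presets, JSON configuration, CSV/JSON serialization and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
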