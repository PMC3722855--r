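Package: viscofit
Title: Viscoelastic Parameter Identification from Ramp-and-Hold Shear Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for identifying linear-viscoelastic (Prony series) shear
    moduli of soft tissue from ramp-and-hold simple-shear tests. Implements
    the recursive hereditary-integral stress update, a parametric hexahedral
    finite-element model of cylindrical and cubic specimens with a
    quasi-static nearly incompressible solver, analytical (1-D) fits with and
    without the loading ramp, finite-element-based fitting by successive
    response-surface methodology with D-optimal designs, a synthetic-specimen
    generator with realistic test noise, and a study pipeline comparing the
    identification approaches (fit mode, specimen shape, specimen height,
    mesh convergence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
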