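Package: cakewash
Title: Integrated Dead-End Filtration and Cake Washing of Drug Suspensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mechanistic simulation and calibration toolkit for the isolation
    of active pharmaceutical ingredients by constant-pressure dead-end
    filtration followed by cake washing. Filtration uses Darcy's law with a
    Carman-Kozeny compressible specific cake resistance integrated to dryland;
    washing offers three mechanisms (ideal piston displacement,
    axial-dispersion washout parameterized by a Peclet number, and well-mixed
    semibatch dilution). Includes Darcy linearization and compressibility
    fits, parameter estimation of sphericity, porosity, medium resistance and
    compressibility index from filtrate volume-time data, built-in mefenamic
    acid and paracetamol case-study scenarios, synthetic observation
    generators, design-space sweeps with knee detection, wash-split
    comparison, and impurity-minimizing wash-plan optimization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
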