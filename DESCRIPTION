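Package: triadspin
Title: Spin Dynamics of Radical Triads and Magnetic Field Effects on
    Reaction Yields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the spin dynamics of a flavin
    semiquinone/superoxide/ascorbyl radical triad in which the quickly
    relaxing superoxide is traced out, leaving a reduced two-radical
    quantum master equation with Haberkorn reaction kinetics. Computes
    singlet recombination and superoxide escape quantum yields as
    functions of magnetic field strength, reaction rate constants and
    molecular orientation, including geomagnetic versus hypomagnetic
    field comparisons (MARY curves, rate maps, orientation averaging for
    protein-bound flavin, and optional random-field electron spin
    relaxation). A small-system solver for the full three-radical model
    verifies the partial-trace reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
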