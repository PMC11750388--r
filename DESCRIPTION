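Package: evodisp
Title: Eco-Evolutionary Dynamics of Parasite Transmission Dispersion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Couples a two-host-type susceptible-infected epidemic model to
    Price-equation dynamics of the mean parasite within-host growth rate, under
    a transmission-virulence trade-off, and computes parasite fitness (the
    effective reproduction number Re) and transmission dispersion (the
    variance-to-mean ratio of Re across infected host types) along epidemic
    trajectories and at endemic equilibria. Includes an explicit multi-strain
    compartmental model used as an independent oracle for the Price-equation
    trait dynamics, scenario presets, scan drivers over host composition and
    host-quality gaps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
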