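Package: popsir
Title: Epidemic Modelling of Popularity Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models event-count popularity time series (such as song download
    curves) as epidemics. Provides deterministic and exact stochastic
    (Gillespie) simulation of the susceptible-infectious-recovered (SIR)
    model, final-size calculus, least-squares SIR trajectory fitting with
    Latin-hypercube multistart, natural cubic spline benchmark fits, a
    relative goodness-of-fit measure with inclusion criteria, genre-level
    parameter summaries, and a calibration experiment that compares
    mechanistic and phenomenological fits on data simulated from the
    mechanistic model itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    readr,
    digest,
    splines,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
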