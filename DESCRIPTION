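Package: sappa
Title: Delay-Coupled Hopf Oscillator Simulations of Anticipatory
    Sensorimotor Synchronization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates rhythmic perception-action coordination with a
    canonical Hopf oscillator that receives delayed recurrent feedback
    (the SAPPA model of strong anticipation). Provides a fixed-step
    Runge-Kutta integrator for the underlying delay differential
    equation, peak-based asynchrony and lead/lag measurement, drivers
    for solo metronome tapping, alternating duet tapping with or
    without auditory feedback, and duet rhythm alternation under
    transmission latencies, plus parameter sweeps over the feedback
    amplitude and delay, grid-search parameter fitting, and attractor
    classification. Results are returned as tibbles with broom-style
    tidiers and ggplot2 autoplot methods, and a command-line interface
    exposes the experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
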