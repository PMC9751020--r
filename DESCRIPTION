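Package: tfusim
Title: Multiscale Simulation of Transcranial Focused Ultrasound Neurostimulation
Version: 0.1.0
Authors@R: person("tfusim", "developers", role = c("aut", "cre"),
    email = "tfusim@example.org")
Description: Couples a two-dimensional acoustic propagation model of a
    simplified human head (water, skull, brain) with an intramembrane
    cavitation point-neuron model (bilayer sonophore mechanics driving a
    regular-spiking Hodgkin-Huxley membrane through cycle-averaged effective
    variables). Produces maximum-pressure and time-averaged-intensity field
    maps for pulsed focused-ultrasound drives, and per-location neural latency
    and firing-rate responses as a function of duty cycle and skull thickness.
    Includes a finite-difference time-domain solver with perfectly matched
    layers, lookup-table construction for the effective-variable neuron model,
    a brute-force co-integration oracle, a multiscale orchestration pipeline,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
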