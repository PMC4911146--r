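Package: pcsn
Title: Continuous-Signal-Coding Spiking Neural Networks with FORCE Learning
        and Path-Integral Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
        email = "author@example.org")
Description: Simulation and training of continuous-signal-coding spiking neural
        networks (CSNs): leaky integrate-and-fire networks whose membrane
        potentials and filtered spike trains jointly encode nonlinear continuous
        reservoir dynamics. Two variants are provided, neurons with saturating
        synapses and neurons with nonlinear dendrites. The package implements
        recursive-least-squares (RLS) and FORCE learning of linear readouts and
        recurrent weights (plastic CSNs, PCSNs), generators for pattern-generation,
        delayed-reaction and instruction-switching benchmark tasks, a stochastic
        pendulum plant with path-integral stochastic optimal control driven by a
        learned spiking world model, and diagnostics such as mean spike rates,
        phase-aligned recall error and the Lorenz tent map.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp (>= 1.0.0), deSolve, jsonlite, stats, utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
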