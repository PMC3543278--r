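Package: QLandscape
Title: Quasi-Attractor Landscapes in Cholinergically Modulated Theta-Neuron Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a two-scale cortical model in which
    units of pulse-coupled excitatory (pyramidal) and inhibitory (fast-spiking)
    theta neurons are wired into a multi-unit associative memory. Provides a
    finite-size stochastic simulator (Euler-Maruyama), its deterministic
    Fokker-Planck mean-field limit (Fourier pseudo-spectral in phase, adaptive
    Runge-Kutta in time), modified-Hebbian inter-unit weights storing binary
    patterns, cholinergic modulation of inhibitory and excitatory synaptic
    strengths as bifurcation parameters, transient glutamatergic top-down drive,
    and the analysis toolbox for the resulting dynamics: pattern overlaps via
    local-peak-held firing rates, staying times at quasi-attractors, largest
    Lyapunov exponents, and classification of the attractor landscape.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
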