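Package: tripartite
Title: Simulation of a Two-Neuron, One-Astrocyte Tripartite Synapse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation and analysis of a conductance-based
    tripartite synapse: a pyramidal neuron and an interneuron, each described
    by Hodgkin-Huxley membrane equations in the shifted-frame convention,
    coupled by excitatory and inhibitory conductance synapses, with an
    astrocyte whose IP3-gated endoplasmic-reticulum calcium dynamics
    (Li-Rinzel model) feed a calcium-dependent current back onto both
    neurons.  Includes a fixed-step fourth-order Runge-Kutta integrator
    implemented in C++, spike-train extraction and burst/delay/distortion
    statistics, and sweep drivers for rheobase, critical synaptic coupling,
    bursting-like-spike region and rate maps, transmission-delay curves and
    information-distortion curves.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
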