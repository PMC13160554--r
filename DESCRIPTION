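Package: olfdrift
Title: Spiking Network Model of Representational Drift in the Early
    Olfactory System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a spiking network model of the main olfactory bulb
    and piriform cortex built from Izhikevich neurons, with adult
    neurogenesis modeled as daily reshuffling of granule-cell synaptic
    weights and a suppression-model spike-timing-dependent plasticity
    (STDP) rule restricted to adult-born granule-cell synapses.  Provides
    a synthetic odor-panel generator, a vectorized network simulator,
    and a representational-drift analysis pipeline: sliding-window firing
    rates, pooled principal-component eigenspaces, full-ensemble and
    reduced-space population-vector correlations, cosine-similarity drift
    rates, and K-nearest-neighbor odor decoding.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
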