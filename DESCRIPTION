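Package: bgbeta
Title: Spiking Basal Ganglia Network Model of Pathological Beta Oscillations
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a spiking network model of the basal ganglia
    (striatal D1/D2 medium spiny neurons, fast-spiking interneurons,
    GPe-TA/GPe-TI pallidal populations and the subthalamic nucleus) built
    from adaptive exponential and adaptive quadratic integrate-and-fire
    neurons with conductance-based synapses, and analyses the emergence of
    pathological beta-band (8-24 Hz) oscillations under dopamine depletion.
    Provides the Complete Model, a two-loop Simplified Model with a tunable
    inter-loop coupling, dopamine-depletion and optogenetic-like
    perturbations, population-size scaling, a Welch spectral pipeline with
    a binomial shot-noise correction, connection-ablation screening, and
    burst-statistics analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    e1071,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
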