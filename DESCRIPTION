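Package: strfcascade
Title: Linear-Dynamical Cascade Models of Auditory Rate Coding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates auditory responses of cortical-level songbird neurons
    with a linear-dynamical cascade: a parametric Gabor spectrotemporal
    receptive field is convolved with a song spectrogram to produce a driving
    current, which is injected into a conductance-based single-compartment
    neuron whose low-threshold potassium current (IKLT) switches it between
    tonic and phasic firing. Includes a synthetic song generator, 1/f^alpha
    noise currents at controlled signal-to-noise ratios, spike extraction,
    and rate-coding analyses (activity-fraction selectivity, total and noise
    entropy, mutual information, coding efficiency), plus experiment drivers
    for paired phasic/tonic ensembles and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
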