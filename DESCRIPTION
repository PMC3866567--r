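Package: cdgamma
Title: Current-Dipole Gamma Rhythms in a Laminar Neocortical Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Biophysical simulation of gamma-frequency rhythms in the equivalent
    current dipole (CD) of a laminar neocortical microcircuit. The package builds
    reduced compartmental Hodgkin-Huxley models of layer 2/3 and layer 5 pyramidal
    cells and fast-spiking basket interneurons, wires them into single-layer or
    two-layer networks with AMPA and GABA-A synapses, and drives them with tonic
    current (strong PING), Poisson synaptic noise (weak PING), or rhythmic
    Gaussian-burst proximal/distal inputs (subthreshold driven gamma). The
    longitudinal current dipole is computed in nanoampere-meters from
    intracellular axial currents, and a waveform-statistics layer provides Morlet
    spectrograms, Welch periodograms, extrema detection, cycle slope ratios,
    spike/PSTH histograms, and high-gamma transient detection, usable on any
    uniformly sampled time series.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
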