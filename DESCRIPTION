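Package: fdgscape
Title: Frequency-Dependent Gain and Ionic-Current Decomposition for
    Conductance-Based Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the spiking frequency preference of
    conductance-based neuron models driven by frozen-noise current
    injections. Generates reproducible frozen white-noise stimuli,
    simulates a single-compartment neuron with labelled ionic currents
    (including switchable slow "human-like" and fast "rodent-like"
    h-current kinetics), estimates the frequency-dependent gain from the
    stimulus/spike-train cross-spectrum on a 1-30 Hz grid, decomposes
    membrane currents into per-timestep inward/outward percentage
    contributions, computes spike-triggered averages of those
    contributions with an isolated-spike criterion, quantifies their
    pre-spike monotonicity, and summarises interspike-interval
    variability including a two-sample coefficient-of-variation test.
    A protocol driver orchestrates multi-trial ensembles across h-current
    conductance scalings, and a text-trace adapter ingests somatic
    recordings exported from NEURON models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
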