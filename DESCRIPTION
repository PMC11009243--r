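Package: ernasim
Title: Mesocircuit Simulation and Waveform Analysis of DBS Evoked Resonant Neural Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying evoked resonant neural activity (ERNA) in the
    subthalamic nucleus during deep brain stimulation. Provides (i) a
    point-neuron STN-GPe mesocircuit simulator with Tsodyks-Markram
    short-term synaptic plasticity, conductance-based integrate-and-fire
    GPe neurons and Ornstein-Uhlenbeck synaptic noise, driven by DBS pulse
    trains; (ii) an analysis pipeline for microelectrode recordings:
    interstimulus segmentation and averaging, P1/P2 peak extraction and
    temporal-dynamics ratios, peristimulus spike histograms, and
    mixed-effects / rank-correlation statistics linking ERNA amplitude to
    neuronal firing; and (iii) a synthetic microelectrode-recording
    generator so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    lme4,
    lmerTest,
    jsonlite,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
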