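Package: behavdyn
Title: Behavior Contagion Dynamics, Information Measures, and
    Psychophysiological Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulators for behavior-adoption dynamics (difference-equation
    diffusion, system-dynamics adoption, SIR compartments, network contagion,
    degree-based mean-field spreading), percolation analytics for contact
    networks with immune-node removal, information-theoretic behavior
    contagion measures (entropy, mutual contagion, channel capacity, maximum
    entropy), and a calibration engine that converts psychophysiological
    index tables (heart-rate variability, electromyography, respiration,
    electrodermal and EEG indexes, self-report scales) into adoption and
    imitation parameters via a stress-threshold rule. Includes a synthetic
    cohort generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
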