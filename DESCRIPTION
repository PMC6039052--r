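Package: spindlenet
Title: Thalamocortical Network Simulation and Sleep Spindle Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Conductance-based simulation of interacting core and matrix
    thalamocortical systems built from Hodgkin-Huxley thalamic relay,
    reticular, pyramidal and interneuron models, together with estimated
    local field potentials, Hilbert-envelope sleep spindle detection, and
    spindle ensemble statistics (density, inter-spindle intervals,
    spatial correlation, core/matrix co-occurrence and onset delays).
    Includes drivers for fanout-ratio and interlaminar-strength parameter
    sweeps and a labeled synthetic burst generator for detector
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    nortest,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
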