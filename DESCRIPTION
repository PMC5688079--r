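Package: restwire
Title: Resting-State Intracranial EEG Connectivity, Wiring Cost and
    Threshold Filtration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-condition (eyes-closed vs eyes-open)
    resting-state intracranial EEG. Extracts instantaneous power and phase
    with complex Morlet wavelets, estimates functional connectivity with
    three measures (windowed Spearman power correlation, intersite phase
    clustering, phase-lag index), weights connectivity by inter-electrode
    Euclidean distance to obtain a wiring-cost matrix, computes binary
    network metrics at a fixed mean-plus-one-standard-deviation threshold,
    sweeps all thresholds in a graph filtration, and contrasts conditions
    with window-level permutation tests. Includes a synthetic coupled
    alpha-oscillator generator with heterogeneous electrode implants so the
    whole pipeline is testable without clinical recordings, and a minimal
    European Data Format (EDF) writer/reader.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
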