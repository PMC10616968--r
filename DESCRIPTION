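Package: eegpipe
Title: Event-Locked Spectral Analysis for Mobile EEG
Version: 0.1.0
Authors@R: person("eegpipe", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Pipeline for event-locked analysis of mobile EEG recorded around
    recurring visual occlusions: synthetic phase-resetting EEG generation,
    channel-quality rejection, zero-phase filtering and re-referencing,
    simplified artifact subspace reconstruction, EEMD/CCA suppression of
    high-frequency muscle artifacts, sync-edge clock alignment and epoching,
    median-based event-related spectral perturbation and inter-trial
    coherence with bootstrap significance masking, and weighted k-means
    clustering of independent components across subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
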