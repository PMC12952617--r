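Package: circavar
Title: Inter-Individual Variability Analysis for Circadian Locomotor Behaviour
Version: 0.1.0
Authors@R: person("Circavar", "Developers", email = "maintainer@circavar.org",
    role = c("aut", "cre"))
Description: Tools to quantify inter-individual variability in circadian
    behaviour of Drosophila from beam-crossing activity monitor recordings.
    Implements reading and writing of DAM2-style monitor files, entrainment
    indexing around light transitions, a periodic two-state hidden Markov
    model of activity with negative-binomial emissions, harmonic time-of-day
    switching probabilities and individual random intercepts (marginal
    likelihood via Gauss-Hermite quadrature), model-implied state-occupancy
    curves and their between-individual variability, circular phase-coherence
    statistics (Von Mises fitting, Watson goodness-of-fit, equal-concentration
    tests), autocorrelation-based rhythmicity scoring, Morlet-wavelet period
    estimation for bioluminescence traces, and bootstrap estimation statistics
    for two-group comparisons. A synthetic actogram generator with known
    ground truth makes every stage testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
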