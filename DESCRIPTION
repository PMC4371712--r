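Package: rmsorn
Title: Reward-Modulated Self-Organizing Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for reward-modulated self-organizing recurrent networks
    (RM-SORN): two-layer binary threshold networks in which a sparse excitatory
    reservoir with inhibitory feedback self-organizes through intrinsic
    plasticity, synaptic normalization and spike-timing-dependent plasticity
    (STDP), and a winner-take-all readout layer learns through reward-modulated
    STDP. Includes seeded generators and scoring rules for eight symbolic
    sequence benchmarks (counting, motion prediction, occluder, memory
    capacity, Markov-85, parity, motion generation, pattern recognition), the
    two-phase snapshot-selection training protocol, supervised (SORN), static
    and random-update comparison baselines, a noise-for-exploration mode, and
    utilities for parameter grid search, experiment replication and neuron
    selectivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
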