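Package: neuroedge
Title: EEG Mental-State Monitoring with a Temporal Shift Transformer and
    Game-Theoretic Edge Resource Allocation
Version: 0.1.0
Authors@R:
    person("Neuroedge", "Developers", email = "neuroedge@example.org",
           role = c("aut", "cre"))
Description: Tools for end-to-end desk-scale simulation of an EEG-based
    mental-state monitoring system running on edge hardware. Provides EEG
    input/output (EDF and delimited matrix dialects) with montage handling,
    an artifact-regression/normalization/filtering/quality-scoring
    preprocessing chain, a temporal shift transformer sequence classifier
    trained by backpropagation in pure R, a Stackelberg leader-follower
    resource-allocation game with closed-form, grid, and swarm solvers, a
    nomadic particle-swarm optimizer, an edge latency-budget and alerting
    simulator, and a seeded synthetic EEG generator so every component is
    testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
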