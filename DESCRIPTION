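Package: sopdual
Title: Discrete-Moment Simulation of Wagner's Sometimes-Opponent-Process
    Memory Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements Wagner's sometimes-opponent-process (SOP) theory of
    stimulus representation as a deterministic discrete-moment simulator.
    Memory elements of each stimulus occupy an inactive (I), primary active
    (A1) or secondary active (A2) state; per-moment transitions implement
    self-generated priming (A1 to A2 decay), retrieval-generated priming
    (associative activation of A2) and opponent excitatory/inhibitory
    associative learning. Paradigm builders reproduce a Y-maze
    spatial-novelty-preference factorial (massed versus spaced exposure
    training crossed with short and long test intervals), a sweep over
    reductions of the A1-to-A2 decay rate modelling GluA1 AMPA-receptor
    subunit deletion, a CS-duration conditioning experiment and repeated
    presentation habituation series. A synthetic-behaviour stage maps model
    states to per-animal arm exploration times, generates noisy cohorts,
    analyses them with resampling statistics (bootstrap, sign-flip and
    permutation tests of the novelty discrimination ratio) and recovers the
    decay parameter from synthetic cohorts by grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
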