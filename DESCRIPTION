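Package: replaynav
Title: Hippocampal Memory-Replay Agents for Grid-World Spatial Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation of a hippocampus-striatum spatial-cognition model in
    which a competitive place-cell network forms a cognitive map and a
    memory-replay mechanism consolidates it: navigation episodes are stored
    as trajectory sequences in a bounded memory vault, failed and successful
    trajectories are spliced at shared place cells into never-traversed
    virtual paths, and reward-associated sequences are replayed through
    temporal-difference updates so that reward signal propagates along whole
    trajectories without eligibility-trace tuning.  Includes discrete Morris
    water-maze environments (open arena, block and U-shaped obstacles, and a
    seeded corridor maze), tabular Q-learning baselines with eligibility
    traces and with uniform random experience replay, comparative experiment
    drivers, and signal-propagation/reactivation map rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
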