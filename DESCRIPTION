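Package: nebflow
Title: Automated Reaction-Path Optimization with the Nudged Elastic Band
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated lifecycle for finding minimum energy paths and
    transition states of small gas-phase molecular rearrangements on
    pluggable potential-energy surfaces. Covers endpoint minimization
    (bounded-step L-BFGS), two-stage permutation-invariant structural
    alignment (joint rotation and assignment), sequential image-dependent
    pair-potential (SIDPP) initial path generation, climbing-image nudged
    elastic band optimization with energy-weighted springs, dimer
    minimum-mode-following saddle refinement, one- and two-dimensional
    path projections, and a content-hash driven stage graph with
    incremental recomputation. Built-in analytic surfaces (Mueller-Brown,
    pairwise Morse clusters) supply fully reproducible test systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
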