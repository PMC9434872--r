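Package: reactbo
Title: Batched Bayesian Optimization over Discrete Reaction Search Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gaussian-process Bayesian optimization over finite, encoded
    candidate tables such as combinatorial reaction scopes and molecular
    libraries. Provides cartesian search-space construction with descriptor
    or fingerprint encoding and correlated-column pruning, a Matern-5/2
    Gaussian-process surrogate with joint posterior sampling, the Expected
    Improvement family of acquisition functions (EI with exploration offset,
    EI-k, exploration-enhanced E3I) alongside Thompson sampling and simple
    mean/variance controls, Kriging-Believer and parallel-Thompson batch
    selection, a seeded multi-replicate evaluation harness with Welch
    comparisons, and synthetic yield-surface generators with known optima
    for benchmarking optimizer robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
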