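Package: traitjudge
Title: Staircase-Controlled Simulation and Reverse Correlation of
    Uncertain Trait Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analyzing two-alternative personality
    trait judgment experiments in which stimulus difficulty is controlled
    by separately assessed standard ratings.  Implements dual weighted
    up-down staircases moving on the evidence diagonal of the self/other
    rating space, density-corrected Gaussian adjective sampling, simulated
    observers with balanced-evidence choice and balanced or
    positive-evidence confidence rules, logistic choice-function fitting
    with per-participant confidence median splits, reverse correlation
    yielding decision and confidence weights, and repeated-measures ANOVA
    with generalized eta squared, including the weight-inversion symmetry
    test.
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
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
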