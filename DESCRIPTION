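Package: spea2rules
Title: Chaos-Embedded Multi-Objective Evolutionary Interval-Rule Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines Pareto-optimal sets of interpretable if-then interval
    rules from numeric trait tables with a chaos-embedded SPEA2
    (strength Pareto evolutionary algorithm) engine.  Rules are
    conjunctions of closed numeric intervals over measured attributes and
    are evolved one-vs-rest against three conflicting objectives
    (accuracy, precision, recall).  Population initialisation and
    mutation draw from a guarded tent chaotic map.  Includes a labelled
    dataset reader with trap-count class derivation, a stratified
    splitter, a synthetic-data generator emulating a cherry-fruit-fly
    infestation survey (including planted-rule datasets with known
    ground truth), structural interpretability metrics, and a
    repeated-experiment harness with per-class statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
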