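Package: birdquiz
Title: Adaptive Birdsong-Identification Quiz Training, Simulated End to End
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to generate, execute and evaluate quiz-style birdsong
    identification training policies on simulated learners. Implements an
    adaptive five-choice quiz engine in which per-species proficiency counters
    drive both the choice of the correct species (with a review-probability
    mechanism for mastered species) and the difficulty of the distracters, a
    baseline engine with uniformly random items, a forgetting-curve learner
    simulator (exponential retention with spacing-dependent consolidation and
    similarity-driven confusion), a randomized two-arm experiment protocol
    (pretest, four 50-question training days, midterm, posttest, delayed test),
    per-species training metrics (question counts, inverse lag time, median
    question interval, accuracy, confusion matrices), a permutation test for
    arm contrasts, and a command-line interface with JSON-lines event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
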