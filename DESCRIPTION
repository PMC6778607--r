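Package: mouselabq
Title: Information-Board Choice Games and the Choice-Quality Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of a cost-benefit information-board
    (Mouselab-style) choice game and its choice-quality analysis. Provides a
    game engine with an explicit credit ledger (per-cell information costs,
    per-step time costs, per-round allocations), seeded synthetic agents
    implementing classic multi-attribute choice heuristics (random,
    exhaustive, take-the-best, satisficing, weighted additive) that emit
    process-tracing event logs, a plain-text trace format with readers and
    writers, per-subject economic metrics (expected value, incorrect-choice
    cost, utility, and the choice-quality index), and cohort summaries:
    descriptive statistics and Pearson correlation matrices with two-tailed
    significance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
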