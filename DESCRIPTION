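Package: refinebandit
Title: Evolutionary Tournaments of Social Learning and Cumulative Culture on a Restless Bandit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulation engine for studying the evolution of
    social learning and cumulative culture. Populations of strategy-driven
    agents face a restless 100-armed bandit and choose each round among
    EXPLOIT, INNOVATE, OBSERVE and REFINE moves; strategies compete under
    death-birth dynamics with payoff-proportional reproduction and mutation.
    Includes the pairwise-invasion and melee contest protocols with staged
    promotion, a plugin interface for strategies (a move rule plus an
    optional model-ranking rule), reference strategies, cultural-diversity
    metrics (amount, Pielou evenness, persistence), a refinement
    stopping-criterion experiment contrasting selective refiners with blind
    copiers, and reproducible seeded runs with manifest-based replay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
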