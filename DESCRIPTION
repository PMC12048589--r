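Package: racas
Title: Simulation and Analysis of the RaCaS Dynamic Reward Schedule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements the RaCaS ("Regularity as Carrot and Stick")
    reward-allocation algorithm for 100-trial two-alternative choice
    tasks under the Choice Engineering Competition constraint of exactly
    25 rewards per side. Provides the scheduler as a pure, deterministic
    state machine, a library of simulated decision-making agents
    (Bernoulli, win-stay/lose-shift, Q-learning, and a
    regularity-seeking heuristic), a reproducible session runner,
    the behavioral metrics used to evaluate choice engineering
    (choice bias, normalized reward difference, observed expectancy,
    exploitation, rolling averages, effect sizes and classical tests),
    canonical session CSV input/output with validation, an adapter for
    external per-trial exports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    readr,
    stats,
    tibble,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
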