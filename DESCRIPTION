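Package: banditmiss
Title: Two-Armed Bandit Trial Simulation with Missing Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates two-armed response-adaptive clinical trials with
    Bernoulli outcomes that are missing at random, and evaluates the
    operating characteristics of ten allocation rules (fixed randomization,
    tuned and raw Thompson sampling, randomized play-the-winner, current
    belief, Gittins index, UCB, randomized UCB, and randomized belief and
    Gittins indices). Includes a dynamic-programming computation of the
    Beta-Bernoulli Gittins index under geometric discounting, a
    mean-imputation remedy for missing outcomes, Monte-Carlo summaries of
    allocation proportion, observed and expected numbers of successes,
    diagnostics for the bias of the sample mean under adaptive sampling,
    and scenario grids with plotting helpers for missingness sensitivity
    studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
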