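Package: netchoice
Title: Network Models of Probabilistic Choice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Represents discrete choice problems as networks of cues and
    alternatives whose binary activation states follow a quadratic
    exponential (Ising) distribution. Alternatives are evaluated by
    Metropolis single spin-flip dynamics; choices are triggered either at
    convergence (the Boltzmann / Luce limit) or at first passage to a
    configuration with a single active alternative (bounded rationality).
    Provides an exact absorbing Markov chain solver for first-passage
    choice probabilities and expected decision times, a Monte-Carlo
    simulator, calibrated fixtures for the endowment effect and the
    similarity, attraction, repulsion, compromise and phantom context
    effects, a phase scan over the inverse-temperature and appeal-weight
    scalings, and checkers for classical rationality properties
    (regularity, Luce's choice axiom, binary utility classes, stochastic
    transitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
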