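Package: sosaspsa
Title: Sentiment Contagion Dynamics with the Modified SOSa-SPSa Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic simulation of sentiment contagion in
    a closed crowd using a three-compartment model (susceptible, optimistic,
    pessimistic) that extends the two-channel SISa framework with direct
    optimist-pessimist interaction. Provides the compartmental right-hand
    sides with frequency- or density-dependent contact terms, trajectory
    integration, algebraic equilibrium location with steady-state identity
    checking and numerical stability assessment, parameter-sweep experiments
    over recovery and spontaneous-generation rates, an exact event-driven
    (Gillespie direct method) stochastic counterpart for mean-field
    verification, and a configuration-driven command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
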