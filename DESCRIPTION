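Package: antbattle
Title: Chemical Reaction Kinetics of Group Battles in Social Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models inter-species battles between social animals (staged ant
    combats between Lasius paralienus and Lasius neglectus) as a mass-action
    chemical reaction network over five "chemical species": lone fighters A
    and B and the gripping groups AB, ABB and ABBB.  Provides the 15-channel
    reaction registry, a deterministic mean-field ODE engine, an exact
    Gillespie direct-method stochastic simulator with a compiled core,
    calibration of the rate constants from event-driven battle logs and
    hourly mortality tables by weighted least squares with a Nelder-Mead
    simplex in log-parameter space, statistical validation of the fitted
    parameter distributions (lognormal, exponential, Weibull likelihoods,
    split-half validation, Wilcoxon rank-sum comparisons), and the supremacy
    phase diagram with its separatrix between the two absorbing outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    fitdistrplus,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
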