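Package: codfba
Title: Dynamic Flux Balance Modeling of Batch Yeast Co-Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dynamic flux balance analysis (DFBA) of microaerobic batch
    co-cultures of a respiratory-deficient Saccharomyces cerevisiae strain
    and wild-type Scheffersomyces stipitis fermenting glucose/xylose
    mixtures to ethanol. Provides stoichiometric network containers with
    SBML import/export, block-diagonal community assembly and a community
    flux balance linear program with parsimonious resolution of alternate
    optima, Michaelis-Menten substrate uptake kinetics with ethanol and
    glucose inhibition, a stiff ODE batch simulator with a dissolved-oxygen
    balance and an ATP-maintenance toggle, an in silico screen for
    respiratory-deficiency knockouts, least-squares calibration of uptake
    parameters, and downstream analyses: inoculum/aeration optimization of
    ethanol productivity, scaled sensitivity analysis of xylose-transporter
    parameters, and the minimum aeration level supporting growth on ethanol.
    Ships a synthetic-data module generating small hand-solvable networks
    and noisy batch datasets so the whole pipeline is testable without
    genome-scale downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
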