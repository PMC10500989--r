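Package: oneopes
Title: OneOPES Replica-Exchange Enhanced Sampling on Analytic Model Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the OneOPES combined enhanced-sampling scheme: a
    ladder of replicas that layers an OPES Explore bias on leading collective
    variables, weak auxiliary-CV OPES biases, and an OPES MultiThermal
    (expanded-ensemble) bias on the potential energy, coupled by
    Metropolis-Hastings coordinate swaps. The method is exercised on built-in
    analytic toy potentials (double wells, a hidden-barrier 2-D well,
    Mueller-Brown, harmonic) integrated with BAOAB Langevin dynamics, so that
    every free-energy estimate can be checked against brute-force quadrature
    oracles. Includes reweighting to free-energy surfaces and basin free-energy
    differences with block-analysis errors, multi-temperature reweighting with
    Van't Hoff fits (enthalpy, entropy, melting temperature), exchange-rate
    diagnostics, demultiplexed continuous trajectories, and PLUMED-dialect
    COLVAR input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
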