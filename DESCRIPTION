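Package: memmtools
Title: Multi-Ensemble Markov Models for Binding Thermodynamics and Kinetics
Version: 0.1.0
Authors@R:
    person("memmtools", "developers", email = "memmtools@example.org",
           role = c("aut", "cre"))
Description: Estimation of multi-ensemble Markov models (MEMMs) from mixtures
    of time-correlated (unbiased) and equilibrium (biased replica-exchange)
    simulation data. Implements the MBAR, TRAM and hybrid TRAMMBAR
    maximum-likelihood estimators with per-ensemble reversible transition
    matrices, unbiased stationary distributions, dissociation constants and
    perturbative free-energy differences; downstream kinetic analysis with
    implied timescales, Chapman-Kolmogorov tests, continuous-time rate-matrix
    estimation (maximum-likelihood and spectral least-squares), mean
    first-passage times and bimolecular association rates; transition path
    theory (committors, reactive fluxes, pathway decomposition); and a
    self-contained two-dimensional protein-ligand binding landscape with
    Metropolis Monte Carlo and Hamiltonian replica-exchange samplers used as a
    fully controlled benchmark system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
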