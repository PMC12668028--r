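Package: spikeMaxEnt
Title: K-Pairwise Maximum Entropy Models of Neuronal Avalanche Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates integrate-and-fire neuronal networks with short- and
    long-term synaptic plasticity that can be tuned to subcritical, critical
    or supercritical avalanche dynamics; bins spike event lists into binary
    rasters and computes the constrained firing statistics (local activities,
    pairwise correlations, population synchrony distribution); infers
    K-pairwise maximum-entropy (generalized Ising) models from those
    statistics by Boltzmann-machine learning with Metropolis Monte Carlo
    sampling; and characterizes the thermodynamics of the inferred models
    (specific heat, susceptibility, finite-size scaling of their maxima, and
    the onset of initial-condition-dependent glassy sampling).
License: MIT + file LICENSE
Encoding: UTF-8
Imports: methods, stats, utils, tools, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
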