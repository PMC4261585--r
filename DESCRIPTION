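Package: mkrates
Title: Maximum-Likelihood Estimation of Evolutionary Rates of Discrete
    Characters on a Phylogeny
Version: 0.1.0
Authors@R: person("mkrates", "maintainers", email = "mkrates@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of evolutionary rates of discrete
    characters (any number of states) on a fixed phylogeny with branch
    lengths. Supports equal-rates, symmetric, all-rates-different,
    general time-reversible and birth-and-death (ladder) transition rate
    matrices as well as user-supplied templates, discrete-Gamma rate
    variation among sites, estimation of prior root-state probabilities,
    forced reversibility, correction for unobservable (all-absent) site
    patterns, branch-specific rate categories given by a '$'-labelled
    Newick dialect, and per-site rate estimation. Includes a forward
    simulator of discrete-character evolution and a command-line
    interface for fitting, likelihood-ratio tests and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
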