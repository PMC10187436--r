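Package: latmix
Title: Lattice Monte Carlo Simulation of Multicomponent Biomolecular Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained lattice Monte Carlo simulation and analysis of
    phase separation in mixtures of prion-like low-complexity domains (PLCDs)
    and homopolymers. Chains are modelled one bead per residue on a periodic
    cubic lattice with a symmetric contact-energy matrix and a mean-field
    electrostatic term based on the chain-pair-averaged net charge per residue,
    sampled in the canonical ensemble with a Metropolis criterion. Analysis
    tools extract coexisting dilute- and dense-phase concentrations from radial
    density profiles and logistic fits, build one- and two-component phase
    diagrams, extract tie lines and classify homotypic versus heterotypic
    dominance, quantify internal condensate organization with a crosslinking
    statistic, and profile chain dimensions across the condensate interface.
    An exact-enumeration oracle for tiny systems supports validation of the
    sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    seqinr,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
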