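Package: icekinetics
Title: Markov State Model Analysis of Heterogeneous Ice Nucleation Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct the kinetics of heterogeneous ice nucleation
    on a crystalline surface from molecular trajectories. Water molecules are
    classified as hexagonal ice, rhombic ice, or liquid with averaged
    Steinhardt bond-order parameters; layer-resolved ice counts in the largest
    nucleus serve as collective variables, selected by a Nystrom/spectral-oASIS
    column-subset criterion; Markov state models are estimated with k-centers
    discretization, reversible maximum-likelihood transition matrices, implied
    timescale and Chapman-Kolmogorov validation, and GMRQ cross-validation;
    PCCA+ lumps microstates into metastable macro-states; transition path
    theory yields committors, reactive fluxes, pathway decompositions,
    transition-state ensembles, mean first passage times and nucleation rates.
    A synthetic-data module generates ideal ice lattices and metastable
    two-pathway kinetic networks with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    igraph
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
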