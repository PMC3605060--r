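Package: knotfold
Title: Folding and Knotting Analysis for Coarse-Grained Protein Chains
Version: 0.1.0
Authors@R:
    person("Knotfold", "Developers", email = "maintainer@knotfold.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse the folding of natively-knotted
    protein chains at one-bead-per-residue resolution.  Implements
    ratchet-and-pawl biased overdamped Langevin dynamics over a smooth
    contact-map collective coordinate, a-posteriori dominant-reaction-pathway
    (Onsager-Machlup) scoring of trial trajectories, Go-type coarse-grained
    force fields with optional non-native (quasi-chemical and Debye-screened
    electrostatic) interactions, Monte Carlo polymer dynamics with
    crankshaft, Cartesian and pivot moves, knot and slipknot detection for
    open chains by Alexander determinants after stochastic closure, and
    folding-pathway heterogeneity and knotting-mechanism analyses.  A
    synthetic-data module generates parametric knots, an open-chain shallow
    trefoil toy native, denatured coil ensembles and scripted kinematic
    fixtures, so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
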