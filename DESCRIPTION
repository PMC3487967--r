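Package: glioabm
Title: Multi-Scale Agent-Based Simulation of Vascularized Brain Tumor
    Growth and EGFR-TKI Treatment
Version: 0.1.0
Authors@R:
    person("glioabm", "developers", email = "glioabm@example.org",
           role = c("aut", "cre"))
Description: Hybrid discrete-continuum simulator of brain tumor growth on a
    two-dimensional lattice.  Each tumor cell carries an EGFR-signaling and
    cell-cycle ODE network that decides its phenotype (migration,
    proliferation, quiescence, death); extracellular glucose, oxygen, TGFalpha,
    VEGF, fibronectin and drug fields evolve by finite-difference
    reaction-diffusion; tumor-induced angiogenesis grows a capillary network
    by probabilistic tip-endothelial-cell migration, branching and
    anastomosis; EGFR tyrosine-kinase inhibitors are delivered through the
    neo-vasculature and block receptor signaling by Michaelis-Menten
    occupancy.  Includes local parameter sensitivity and robustness analyses
    of the signaling network and whole-model outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
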