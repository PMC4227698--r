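Package: scblock
Title: Single-Channel Kinetics of Open-Channel Blockade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and kinetic analysis of single-channel patch-clamp
    recordings of ligand-gated ion channels under open-channel blockade.
    Builds aggregated Markov gating schemes with sequential pore block,
    simulates cell-attached recordings (exact continuous-time Markov
    dwell simulation, Gaussian filtering, noise), idealizes sampled traces
    by a segmented k-means hidden Markov procedure, estimates rate
    constants by maximum interval likelihood, and summarizes dose- and
    voltage-dependent blockade kinetics (blocking and unblocking rate
    constants, equilibrium dissociation constants). Includes a Bertz
    molecular-complexity module for comparing blocker structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    ChemmineR,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
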