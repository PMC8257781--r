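Package: eqsim
Title: Modeling and Analysis of Gene Dosage Compensation Circuits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic steady-state and stochastic models of plasmid-borne
    gene circuits for dosage compensation in transiently transfected mammalian
    cells: unregulated promoters, microRNA incoherent-feedforward (IFF)
    control, TetR transcriptional negative feedback (NF) with leaky
    repression, and the combined Equalizer architecture. Provides the
    inverse-log-sensitivity compensation metric with second-order
    finite-difference stencils, population-level coefficient-of-variation
    prediction over a fitted log-normal plasmid copy-number distribution,
    Gillespie stochastic simulation, estimators for the copy-number
    distribution, TetR leakage, and miRNA-target affinity, and a synthetic
    flow-cytometry data generator with gating, binning, CV, and Fano-factor
    analysis so the whole workflow runs end-to-end without external data.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
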