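Package: pepgamd
Title: Dual-Boost Gaussian Accelerated Molecular Dynamics for Peptide
    Binding at Toy Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the dual-boost Peptide Gaussian accelerated
    molecular dynamics (Pep-GaMD) enhanced-sampling method end-to-end at
    desk scale: harmonic boost potentials with adaptive threshold and
    force-constant selection, Langevin (BAOAB) dynamics on analytic model
    potentials and a coarse bead peptide-receptor system with the
    essential-peptide energy decomposition, cumulant-expansion energetic
    reweighting to second order with bin-occupancy cutoffs and
    boost-distribution diagnostics, potential-of-mean-force construction,
    low-energy state identification and activation-state classification,
    and hierarchical agglomerative structural clustering with per-cluster
    reweighted free energies. Exact Boltzmann answers from dense
    numerical quadrature on the analytic potentials serve as oracles for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
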