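Package: cgbind
Title: Coarse-Grained Simulation of Conformational-Transition-Coupled Ligand Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how repeated domain opening and closing of a
    two-state enzyme helps substrates escape non-native binding poses and reach
    the native pose. Implements a residue-level structure-based (Go-type) model
    with a double-basin interface potential, explicit multi-bead ligands with
    native, non-native (ruggedness-controlled) and excluded-volume interactions,
    Langevin dynamics, parallel cascade selection sampling, umbrella sampling
    with multistate (MBAR) reweighting, and censored maximum-likelihood mean
    first-passage-time estimation. Ships a synthetic two-conformation toy enzyme
    generator so the full pipeline runs without external structure files;
    crystal-structure pairs in PDB format are supported through the same loader.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
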