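Package: grooveDock
Title: Grid-Based Flexible Peptide Docking for MHC Binding Grooves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for docking flexible peptide ligands into major
    histocompatibility complex (MHC) class I and class II binding grooves.
    Receptor interaction fields are precomputed on a 1 Angstrom grid over a
    standardized docking box, peptides are sampled in internal coordinates
    (backbone and side-chain torsions plus a rigid-body placement) by a
    biased Monte Carlo search with Metropolis acceptance at 300 K, and
    docked poses are refined at the interface and scored with weighted
    physics-based energy terms. Includes pose evaluation by nonameric-core
    C-alpha RMSD, binding-register detection, dataset non-redundancy
    filtering, and a deterministic synthetic mini-groove generator so the
    whole pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
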