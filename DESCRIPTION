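Package: gifp
Title: GPCR Ligand Interaction Fingerprints and Functional Class Prediction
Version: 0.1.0
Authors@R:
    person("gifp", "developers", email = "gifp@example.org", role = c("aut", "cre"))
Description: Toolkit for structure-based analysis of G protein-coupled receptor
    (GPCR) ligand complexes. Reads single-chain receptor/ligand complexes from
    PDB files, attaches Ballesteros-Weinstein (BW) generic residue numbering
    from annotation tables, detects and types ligand-residue contacts with a
    distance-based interaction score, builds receptor-weighted interaction
    frequency fingerprints, converts contacts into BW-indexed interaction
    profiles with explicit missing-position semantics, trains a random-forest
    classifier of ligand function (agonist, antagonist, inverse agonist,
    inactive) with merged-active and majority-rule pose voting, and evaluates
    docked poses with alpha-carbon superposition and symmetry-aware ligand
    RMSD. A synthetic fixture generator makes every stage testable without
    external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
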