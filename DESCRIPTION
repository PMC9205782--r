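Package: larkscreen
Title: Structure-Based Screening of Missense Mutations in Low-Complexity
    Amyloid-Like Kinked Segments
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies missense mutations predicted to convert reversible,
    kinked-backbone amyloid segments (LARKS) into irreversible pleated
    steric zippers.  Provides fixed-backbone threading of hexapeptide
    sequence windows onto kinked and pleated fibril templates with discrete
    rotamer packing and a decomposed packing energy; an end-to-end screen
    that scans protein sequences for LARKS windows, maps variant tables
    onto them and scores wild-type/mutant zipper-energy differences; and
    geometric analysis of fibril structures (strand/sheet detection,
    steric-zipper class 1-8 assignment, pleated/extended/kinked backbone
    classification, buried interface area).  Includes seeded generators for
    synthetic low-complexity proteomes, variant tables and idealized
    steric-zipper assemblies of all eight symmetry classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
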