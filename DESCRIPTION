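Package: ssphotolysis
Title: Disulphide Photolysis Candidate Analysis and UV Photochemistry Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify disulphide bonds in protein structures that are
    candidates for ultraviolet-light-induced photolysis and to quantify the
    accompanying photochemistry. Reads PDB-format structures, detects cystines,
    computes their chi1-chi5 dihedrals, 20-class stereochemistry labels
    (e.g. -RHStaple), torsional strain energies and Shrake-Rupley solvent
    accessible surface areas, and measures shortest-distance proximity between
    disulphides and tryptophan/tyrosine rings as well as tyrosine-tyrosine
    dityrosine crosslink geometry. Fits single-exponential photobleaching and
    thiol-formation kinetics and sloping-baseline Boltzmann thermal melts,
    implements Ellman free-thiol and extinction-coefficient arithmetic, and
    analyses multi-model structural ensembles (superposition, per-residue
    fluctuations, unit-integral solvent-exposure distributions). Includes
    seeded synthetic-data generators for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
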