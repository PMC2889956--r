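Package: mitorder
Title: Mitogenome Gene-Order Rearrangements, Parsimony Event Mapping, and
    Control-Region Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of vertebrate mitochondrial
    genome organisation, motivated by the rearrangement-rich mitogenomes of
    acrodont lizards (Agamidae and Chamaeleonidae). Models signed,
    linearized gene orders against the typical vertebrate arrangement,
    encodes discrete rearrangement characters (IQM/QIM tRNA cluster order,
    tRNA-Pro position and orientation, control-region duplication,
    light-strand replication origin presence, tRNA-Pro anticodon), maps
    rearrangement events onto a rooted phylogeny by Sankoff/Fitch parsimony
    with most-parsimonious-reconstruction enumeration, annotates
    control-region structure (ETAS, central conserved boxes, CSBs, tandem
    repeats, and the two AT-rich repeat classes of chamaeleonid control
    regions), and provides gene-identification heuristics (vertebrate
    mitochondrial translation with polyadenylation-completed stops,
    cloverleaf-based anticodon extraction, stem-loop detection for the
    light-strand replication origin). A seeded synthetic-data generator
    with ground-truth manifests makes every stage testable without
    sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
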