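Package: edgotyper
Title: Edgotype Classification and Fold-Difference Analysis on Structurally
    Resolved Protein Interactomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structural interactomes and structural proteomes from
    coordinates and sequence alignments, maps missense and nonsense mutations
    onto canonical protein sequences by flanking-sequence matching, classifies
    missense mutations into edgotypes (quasi-wildtype, edgetic, quasi-null)
    from binding and folding free-energy changes and relative solvent
    accessibility, and quantifies the deleteriousness of node-removal
    mutations with fold-difference statistics, threshold sweeps, allele
    frequency bins, and coverage-confounder analyses. Ships a fully seeded
    synthetic-data generator (toy proteomes, dimer coordinates, mutation
    catalogs with ground truth) so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
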