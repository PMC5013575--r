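Package: cliquescreen
Title: Ligand-Based Virtual Screening by Maximum-Clique Common Substructure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand-based virtual screening of small-molecule libraries in
    Tripos MOL2 format. A reference ligand is compared with every library
    molecule (and conformer) by detecting their maximum common substructure
    as a maximum clique on a 2D (topological) or 3D (geometric) product
    graph, solved exactly with a colouring-bounded branch-and-bound.
    Hits are ranked by the graph Tanimoto coefficient, superposed onto the
    reference over the matched atoms (Kabsch least squares), and written as
    a ranked list plus aligned MOL2 files annotated with the matched atom
    pairs. Includes a deterministic synthetic-molecule generator so the
    whole pipeline is testable without external databases, and a
    command-line entry point for shell use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    igraph,
    ggplot2,
    generics,
    optparse,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
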