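Package: tcforge
Title: Linker-Constrained Modeling and Scoring of PROTAC Ternary Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles models of POI-PROTAC-E3 ligase ternary complexes by
    using the degrader linker as a geometric constraint: the warhead and E3
    ligand are kept in their native binding poses, a full-length linker is
    attached to each half-complex, the two half-complexes are joined by rigid
    superposition of their linker copies, and the merged model is refined by
    staged energy minimization.  Ranks degraders with an interaction-energy
    score summed over the protein-binding moieties, summarises protein-protein
    interfaces (hydrogen bonds, salt bridges, nonbonded contacts, buried
    surface), and validates models against reference structures by backbone
    and degrader heavy-atom RMSD.  Includes a seeded generator of synthetic
    toy receptor/degrader systems with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    igraph,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
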