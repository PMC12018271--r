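Package: dualscreen
Title: Design and Analysis of Dual-Guide CRISPRi Genetic Interaction Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for combinatorial dual-guide CRISPR interference screens
    aimed at mapping genetic interactions and synthetic lethality. Covers
    tiered guide selection and mismatch-variant rules for combinatorial
    library design, exact protospacer matching of paired reads into an
    element-by-sample count matrix, median-ratio normalization anchored on
    non-targeting constructs with pseudo-counted log fold changes, a
    hierarchical guide-efficacy/gene-effect/pair-interaction model with
    lambda-scaled sensitive and strong interaction scores, downstream
    synthetic-lethal network construction, profile clustering and embedding,
    and a fully parameterized screen simulator for end-to-end validation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    Biostrings,
    DESeq2,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'dualscreen-package.R'
    'AllClasses.R'
    'counting.R'
    'io.R'
    'library-design.R'
    'model.R'
    'network.R'
    'normalize.R'
    'oligo.R'
    'scores.R'
    'simulate.R'
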