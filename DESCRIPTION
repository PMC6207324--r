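Package: gemforge
Title: Genome-Scale Metabolic Model Reconstruction, Curation and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolbox for constraint-based metabolic modelling: de novo draft
    reconstruction of genome-scale metabolic models (GEMs) from pathway-database
    bundles by protein homology and KEGG Orthology annotation, template-based
    reconstruction via bidirectional best hits, cross-database model combination
    with namespace unification, gap analysis and MILP gap filling, and simulation
    by flux balance analysis, single-gene essentiality, growth-media screening and
    flux scanning with enforced objective function (FSEOF). Models are read and
    written as SBML L3V1 with the FBC v2 package, diff-friendly canonical YAML,
    and tab-separated flat text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    xml2,
    yaml,
    stats,
    utils,
    tools,
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
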