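Package: dtiscreen
Title: Drug-Target Interaction Screening for Antibacterial Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for computational drug repositioning
    against bacterial pathogens. Prioritizes putative drug targets from a
    protein-protein interaction network by combining subgraph centrality
    (closed-walk spectral centrality) with betweenness centrality, featurizes
    drug-target pairs with 755 descriptors (20 amino-acid composition, 240
    Moran autocorrelation and 147 CTD protein descriptors; 323 molecular
    descriptors including MACCS keys and E-state fingerprints), trains and
    validates a random-forest interaction classifier, and ranks all-against-all
    candidate pairs by positive-class probability. Includes a synthetic-data
    generator so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    igraph,
    ChemmineOB,
    Biostrings,
    ranger,
    pROC,
    withr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
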