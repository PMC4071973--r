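Package: TRAPdiv
Title: Diversity Analysis of Dominant Molecular Marker Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genetic diversity analysis for dominant molecular markers
    (TRAP, SRAP, ISSR and similar band-based fingerprints) scored as binary
    presence/absence matrices. Provides a validated container for band
    matrices grouped by primer combination, per-primer polymorphism
    statistics (polymorphism information content and marker index),
    pairwise Jaccard similarity, UPGMA dendrograms with threshold-defined
    cluster cuts and Newick export, principal coordinates analysis with
    Gower double-centering, and a synthetic band-matrix generator with
    planted population structure for validating every pipeline stage
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan,
    mclust,
    jsonlite,
    optparse
biocViews: Clustering, Genetics, PrincipalComponent, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
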