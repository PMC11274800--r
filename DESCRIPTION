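Package: libprof
Title: Profiling, Diversity and Activity Modelling of Focused Chemical Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A cheminformatic pipeline for building and critically comparing
    focused screening libraries. Provides library curation and
    standardization, physicochemical and drug-likeness profiling (QED,
    synthetic accessibility, ESOL solubility), a range-based de novo scoring
    function, RECAP fragmentation with growing-site annotation, MaxMin
    diversity selection, Bemis-Murcko scaffold diversity statistics
    (cyclic-system-retrieval curves, scaled Shannon entropy, consensus
    diversity plots), chemical-space embeddings (PCA, t-SNE), and an
    activity-classification workflow with distance-to-model confidence
    estimation. Synthetic data generators make every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    kernlab,
    methods,
    ranger,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
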