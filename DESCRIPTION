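Package: polysomeFate
Title: Fraction-Resolved Translational Fate Analysis for Polysome
    Profiling Time Courses
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing low-input polysome-profiling time courses
    in which each sucrose-gradient fraction (F1-F10) is sequenced
    separately across developmental stages. Raw fraction counts are
    assembled into free (F1-F2), monosome (F3-F5), polysome (F6-F10) and
    whole-transcriptome layers; fuzzy c-means clustering of standardized
    profiles resolves per-stage translational-selectivity modes and
    temporal clusters; downstream analyses track gene flows between
    stages, monosome-to-polysome cluster overlaps, delayed translational
    activation lags, polysome-versus-monosome occupancy switches, and
    stage-lagged correlation with proteome, poly(A) tail-length and m6A
    companion data. A seeded negative-binomial simulator with planted
    translational states provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
biocViews: RNASeq, Sequencing, Clustering, GeneExpression, Translation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
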