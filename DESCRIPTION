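Package: compostcoop
Title: Cohesion, Co-Occurrence Networks and Mutualism Screening for
    Composting Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for microbial communities under deterministic
    temperature stress, as in full-scale composting: null-model-corrected
    cohesion (taxa-shuffle null, per-taxon connectedness, per-sample
    positive/negative cohesion), random-matrix-theory thresholded
    co-occurrence networks with Maslov-Sneppen null ensembles and Zi/Pi
    node roles, a four-criteria keystone-taxon screen backed by random
    forest permutation importance, abundance-weighted rrn copy number
    (mean copy number) with multiple linear regression against
    temperature and nutrients, KEGG-style module completeness scoring
    and functional grouping of genomes, and polar-angle classification
    of pairwise co-culture interactions. A synthetic-data generator
    emulates the composting study design (piles, time points,
    temperature-tracking guilds, genome groups, mono/co-culture yields)
    with ground-truth labels so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
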