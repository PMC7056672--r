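Package: microgdm
Title: Gut-Microbiome Case-Control Analysis and Prediction of Gestational
    Diabetes from 16S Count Tables
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible reimplementation of a matched
    case-control gut-microbiome workflow for early-pregnancy prediction of
    gestational diabetes mellitus (GDM) from 16S OTU/genus count tables:
    rare-feature filtering, rarefaction, taxonomic aggregation, seven
    alpha-diversity indices with group tests, four beta-diversity distances
    (Jaccard, Bray-Curtis, unweighted and weighted UniFrac) with PCoA and
    PERMANOVA, LEfSe-style differential-abundance effect sizes,
    SparCC compositional correlation networks, Spearman correlation of taxa
    with clinical indices, and a forward-selection linear-discriminant
    classifier with leave-one-out cross-validation, ROC/AUC with DeLong
    confidence intervals, and external validation.  A synthetic-cohort
    generator with known ground truth makes every stage testable without
    access to deposited sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phyloseq
Config/testthat/edition: 3
RoxygenNote: 7.3.3
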