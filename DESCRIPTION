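Package: colonykin
Title: Colony-Level Kinship, Mating System and Population Structure for
    Haplodiploid Social Insects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for colony-level genetic analysis of haplodiploid social
    insects genotyped at codominant (microsatellite-style) markers:
    reconstruction of queen and mate genotypes from worker genotypes by
    parsimony over (queens, alien workers, fathers), mating-frequency
    classification, Queller-Goodnight and maximum-likelihood pairwise
    relatedness, Weir-Cockerham F-statistics with a standard
    differentiation classification, a one-sided two-sample
    Kolmogorov-Smirnov test of non-random mating against the exhaustive
    cross-pair null, and a seeded haplodiploid colony simulator providing
    ground truth for every stage.  Genotype tables are read and written in
    CSV dialects and the Genepop text format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
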