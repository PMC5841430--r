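Package: msatmix
Title: Microsatellite Population Genetics for Mixed-Ploidy Yeast Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing large microsatellite surveys of clonal,
    mixed-ploidy microbial populations such as the wine spoilage yeast
    Brettanomyces bruxellensis. Implements Bruvo's stepwise-mutation-aware
    genotype distance with genome addition/loss models, ploidy inference
    from maximum allele counts, clone collapse, neighbour-joining and UPGMA
    dendrograms with partition-based node reliability, classical
    multidimensional scaling and successive K-means cluster selection,
    chi-square extraction of a core diploid genotype from diploid-triploid
    complexes, distance-based AMOVA, Mantel tests against geographic
    distance, Weir-Cockerham pairwise FST, simplex-constrained matrix
    factorization for ancestry with held-out cross-entropy model choice,
    and growth-curve classification of sulfite (SO2) tolerance. A seeded
    synthetic generator of diploid-triploid complexes and dose-response
    growth curves with known truth supports validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
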