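Package: f2binmap
Title: Ultra-Dense Bin Map Construction and Trait-Locus Mapping for F2
    Resequencing Data
Version: 0.1.0
Authors@R:
    person("Map", "Builder", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds ultra-dense recombination bin maps from whole-genome
    resequencing genotype calls of an F2 intercross and maps a monogenic
    trait locus on them. Provides a synthetic-data generator for the full
    cross design (homozygous founders, recombinant gametes, Poisson read
    depth with per-read error, a fully penetrant recessive locus, and an
    optional genomic deletion line), parent-unique SNP filtering and
    classification, depth-aware six-symbol genotype coding with
    hidden-Markov error correction, bin collapsing with segregation
    tests, two-point EM recombination fractions, linkage grouping and
    regression-style bin ordering with Kosambi distances, a penetrance
    likelihood genome scan with permutation LOD thresholds and
    co-segregation scoring, and zero-coverage deletion detection with
    amplicon presence prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
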