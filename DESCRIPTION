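Package: sgsd
Title: Spatial Genetic Structure and Gene Dispersal from Georeferenced
    Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genetic analysis of georeferenced
    codominant (microsatellite) genotype tables: sample-level quality
    control and spatial grid subsampling, genetic diversity statistics
    (expected and observed heterozygosity, effective allele number,
    rarefied allelic richness, inbreeding coefficient with permutation
    test), pairwise FST and RST with an allele-size permutation test,
    maximum-likelihood EM genetic clustering with AIC model selection,
    Loiselle kinship and fine-scale spatial genetic structure analysis
    (kinship-distance regression, Sp statistic, location permutation
    test), indirect estimation of gene dispersal distance and
    neighbourhood size under isolation by distance, and selfing-rate
    estimation from identity disequilibrium. Includes spatially explicit
    forward-in-time simulators of microsatellite genotypes for validating
    every estimator by parameter recovery, and a config-driven pipeline
    reproducing the full analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
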