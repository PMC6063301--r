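Package: altiscan
Title: Genome-Wide Scans for High-Altitude Adaptation and Demographic
    Inference in Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting genomic signatures of
    high-altitude adaptation in structured population panels: quality
    control of SNP-array genotypes, Spearman correlation of derived
    allele frequency with altitude, kinship-corrected mixed-model
    association (EMMAX approximation), the Population Branch Statistic
    with empirical thresholding, Fisher's combined-P integration and
    candidate-region clustering. Companion demographic statistics
    include runs of homozygosity, inbreeding coefficients, LD-decay
    effective population size and divergence times, f3/D statistics
    with weighted block jackknife, and the Mantel test. A synthetic
    genotype simulator (Balding-Nichols drift, altitude-coupled
    selection, haplotype-mosaic LD, planted autozygosity) provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
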