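Package: invscan
Title: Detection and Population-Genetic Analysis of Chromosomal Inversion
    Polymorphisms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A genome-scan workflow for megabase-scale inversion
    polymorphisms segregating in natural populations. Detects candidate
    inversions from population genotype matrices with a local-PCA/MDS
    window scan, genotypes individuals from the three-cluster structure of
    region PCA, and validates calls with linkage disequilibrium, windowed
    Hudson F_ST, and recombination-rate estimates from F2 intercross
    crossover counts. Includes mutational-load statistics (pN/pS,
    piN/piS), breakpoint annotation tests, a two-deme Wright-Fisher
    migration-selection simulator with parameter rescaling, maximum
    likelihood hybrid-zone cline fitting with AICc model choice, additive
    genotype-phenotype association, and synthetic-data generators with
    truth tables so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
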