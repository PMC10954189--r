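Package: zmethqtl
Title: Sex-Differential Methylation and Methylation QTL Mapping on the Avian Z Chromosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying how DNA methylation is regulated on the
    avian Z chromosome in an advanced intercross. Builds 1-kb window
    methylation phenotypes from binned sequencing coverage, scans for male- and
    female-hypermethylated (MHM/FHM) blocks from per-window sex statistics,
    maps methylation and expression QTL by Haley-Knott interval mapping with
    sex-interactive covariates and hemizygous-Z genotype handling, derives
    permutation significance thresholds, aggregates trans QTL into hotspots by
    shared peak marker and overlapping confidence intervals, correlates
    methylation with gene expression under sex-stratified models, and orients
    significant methylation-expression pairs causally with single-anchor
    structural equation model comparisons (LEO.NB scores). Ships a synthetic
    advanced-intercross generator (ZW inheritance, Haldane recombination,
    negative-binomial window counts, planted effects) so every stage is
    testable without raw data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
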