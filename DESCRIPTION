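Package: varburden
Title: Cross-Population Rare-Variant Overload, Density and Linkage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the population-genetic characterisation of
    rare missense variant overload in a candidate gene. Reconstructs 2x2
    allele-count tables from gnomAD-style per-population frequency tables and
    computes per-variant cross-population enrichment odds ratios with
    confidence intervals and Fisher exact tests; aggregates allele frequencies
    into gene-level burden odds ratios against CDS-length-matched control
    genes with Benjamini-Hochberg adjustment and percentile ranking; profiles
    missense-variant density along the coding sequence with a sliding window,
    calls low- and high-density (constrained) regions against
    population-scaled expected-count thresholds and scores cross-population
    profile similarity; and estimates pairwise linkage-disequilibrium r2 from
    phased haplotypes or unphased genotypes via EM. A seeded synthetic-data
    generator with known ground truth makes every stage testable offline.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
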