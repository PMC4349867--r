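Package: sectorloh
Title: Mapping and Classification of Mitotic Loss-of-Heterozygosity Events
    in Sectored Yeast Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, classifies and statistically analyses mitotic
    loss-of-heterozygosity (LOH) events in paired daughter-cell ("sectored
    colony") samples genotyped by allele-specific SNP-array hybridization
    ratios. Provides per-marker genotype calling, smoothing and run-length
    segmentation; pairing of the two sectors of a colony and classification
    of recombination events (crossovers with or without associated gene
    conversion, 3:1 and 4:0 conversion tracts, break-induced replication,
    deletions, aneuploidy) with single- versus double-sister-chromatid-break
    assignment; conversion-tract length statistics with bootstrap confidence
    intervals; Fisher exact, Mann-Whitney and chi-square tests; genomic
    element enrichment at LOH breakpoints with step-up false-discovery-rate
    correction; and a synthetic-data generator that plants ground-truth
    recombination events in a hybrid diploid genome so every pipeline stage
    is verifiable end to end.
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
    utils,
    yaml
Suggests:
    IRanges,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
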