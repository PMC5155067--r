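Package: bintrans
Title: Genome-Resolved Metatranscriptome Analysis for Binned Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-resolved metatranscriptomics downstream of assembly,
    binning and read alignment: taxonomy assignment to genome bins by best-hit
    voting with averaged amino-acid identity, lowest-common-ancestor labeling of
    unbinned scaffolds, KEGG-Orthology/EC-number reconciliation for enzyme
    classification with identity- and coverage-thresholded EC transfer, RPKM
    normalization and aggregation of transcription to bins, phyla and enzyme
    classes, top-transcriber share statistics, community diversity metrics
    (richness, Shannon, Pielou) with singleton removal, Bray-Curtis/UPGMA
    abundance trees, and respirometry (CO2 evolution rate) integration. A
    synthetic community generator with planted ground truth makes the whole
    pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    ape,
    vegan,
    pracma,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
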