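Package: rilmap
Title: Genetic Linkage Maps from Recombinant Inbred Line Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Construction and diagnosis of genetic linkage maps from
    biparental recombinant inbred line (RIL) genotype matrices, as produced
    by genotyping-by-sequencing (e.g. RAD-seq) and array assays. Provides
    marker and line quality control, flanking-call imputation and
    recombination binning, single-linkage grouping, marker ordering by
    recombination-event counting (RECORD-style greedy insertion with
    window rippling), singleton error correction, Kosambi map distances,
    segregation distortion and distortion-region detection, Chakravarti
    genome-length and coverage estimates, and comparison of the genetic map
    against a physical genome assembly (per-group and local Spearman
    collinearity, inversion flagging, scaffold anchoring, and a cM/Mb
    recombination landscape with hotspot and coldspot calls). Includes a
    meiosis-level RIL population simulator with known truth for validating
    the pipeline, and a bundled reference summary of the CPR-01 chickpea
    intraspecific map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
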