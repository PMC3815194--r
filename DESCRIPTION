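Package: intronarray
Title: Intron Retention Analysis for Strand-Specific Tiling Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for transcriptome-wide intron retention
    analysis of strand-specific tiling microarray data: probe tiling across
    both genome strands, feature-to-core-probe mapping with an intron
    eligibility filter, RMA-style preprocessing (background correction,
    quantile normalization, median-polish summarization), intron/exon
    retention ratios with Mann-Whitney time-course tests and fold-change
    exceedance counts, moderated-t differential expression with
    Benjamini-Hochberg correction, and qPCR absolute/relative quantification
    from dilution-series standard curves. Includes a synthetic-data generator
    with known ground truth emulating a drug-induced splicing-inhibition
    time course.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    limma,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
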