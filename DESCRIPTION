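Package: rrbsdmr
Title: Simulated RRBS Methylomes and Sliding-Window DMR Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for reduced representation bisulfite
    sequencing (RRBS) studies of T-cell methylomes: in silico MspI
    digestion, fragment size selection, directional bisulfite read
    simulation with known ground truth, collapsed-alphabet read placement
    and per-cytosine methylation calling (CpG/CHG/CHH), a sliding-window
    differentially methylated region (DMR) caller combining pooled Fisher
    exact tests with fold-change and hypomethylation filters and iterative
    merging of interdependent regions, sample-level methylome comparison
    (site matrices, Pearson correlation, PCA, context-by-feature
    summaries), DMR-to-gene annotation with local hypergeometric gene-set
    enrichment, targeted-amplicon (TSDR-style) methylation summaries with
    the yellow-green-blue percent color code, and suppression-assay
    quantification (standard-cell dilution counting, relative expansion
    quotients, CFSE dilution fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    fgsea,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
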