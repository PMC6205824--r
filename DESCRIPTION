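Package: ripnet
Title: AGO2 RIP-Seq Binding-Site Calling and Differential
    Transcription-Factor Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis chain for dissecting microRNA regulation from
    AGO2-RIP, small-RNA and time-course RNA sequencing: binding-site
    calling by recursive summit splitting of read pileups with
    all-replicate consensus and 3'UTR annotation, expression-normalized
    target filtering by three-way intersection, signed weighted
    topological overlap (wTO) transcription-factor networks with
    bootstrap link probabilities, differential network classification
    into common/different/specific links, self-organizing-map clustering
    of fold-change trajectories, developmental-atlas correlation
    profiling, and housekeeping-normalized miRNA activity ranking.
    Includes a seeded synthetic-data generator with planted ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
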