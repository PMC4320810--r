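Package: probelnc
Title: Discovery and Regulatory Profiling of lncRNAs from Repurposed Microarray Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for identifying long non-coding RNAs
    (lncRNAs) by reannotating expression microarray probes against merged
    transcript catalogs, validating them with TSS-seq tag clusters and
    chromatin (H3K4me3/H3K4me1/PolII) evidence, classifying them by position
    relative to coding genes and by enhancer-like versus promoter-like
    chromatin signatures, integrating stimulation-induced expression changes
    across many microarray datasets with a robust rank aggregation statistic,
    and associating regulated lncRNAs with neighboring genes and
    transcription-factor binding. Includes a synthetic-data generator with
    planted truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
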