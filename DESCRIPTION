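Package: sRNAstage
Title: Stage-Wise Small RNA Profiling with Exact-Test Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for stage-wise small-RNA sequencing
    analysis of plant somatic embryogenesis: structural read cleaning and
    unique-tag collapsing, exact-match mapping with a priority-cascade
    annotation (rRNA > known miRNA > piRNA > repeat > exon > intron),
    category/length/first-base composition profiling, reads-per-million
    normalisation with the Audic-Claverie exact test for two-library counts,
    and rule-based stage-presence expression-pattern classification with
    abundance flags and four-set Venn partitions. Includes a synthetic-data
    generator with known ground truth (planted categories, patterns,
    fold changes and contaminants) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
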