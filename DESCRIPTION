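Package: twindmr
Title: Sliding-Window Differential Methylation Analysis for Discordant Twin Bisulfite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for two-sample differential DNA methylation
    analysis of reduced-representation bisulfite sequencing (RRBS) data from a
    disease-discordant monozygotic twin pair. Implements sliding-window
    Wilcoxon rank-sum calling of differentially methylated regions (DMRs) from
    per-cytosine coverage reports, genomic and promoter annotation of DMRs
    against gene models, overlap with transcription-factor binding sites, and
    clinical-cohort validation statistics (clone bisulfite summaries, Fisher's
    exact association, methylation-expression correlation). Includes a
    seeded synthetic methylome generator with planted DMRs for benchmarking.
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
    GenomicRanges,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
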