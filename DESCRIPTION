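Package: barseqtools
Title: Bar-Seq Fitness Profiling of Pooled Deletion Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pooled-library fitness screens read out by
    barcode sequencing (Bar-seq). Converts indexed FASTQ reads into per-mutant
    count tables, computes growth-inhibition (GI) scores from normalized log2
    control-to-treatment count ratios scaled by pool doublings, calls
    treatment-sensitive mutants with robust Z-scores (median/NIQR) and
    tail-area false discovery rates from a half-normal empirical null, and
    summarises hit lists by Fisher overlap statistics, average-linkage
    clustering of GI profiles under uncentered-correlation distance, and
    hypergeometric gene-set over-representation. Includes a generative
    simulator of pooled competitive growth with planted sensitivity effects,
    multinomial read sampling and substitution errors, used as ground truth
    throughout the test suite. Also provides microculture growth-curve rate
    fitting for selecting screening doses in a target inhibition band.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
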