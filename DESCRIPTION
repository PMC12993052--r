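Package: ssrcurate
Title: Curation of Multi-Allelic SSR Fingerprints in Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deduplicating and curating microsatellite (SSR)
    genotype collections such as fruit genebanks. Computes tolerance-aware
    Dice-Sorensen distances between multi-allelic fingerprints, clusters
    samples into named molecular groups at a distance cut-off, compiles a
    majority-rule representative ("synthetic") fingerprint per group with
    explicit tie flagging and rule-based resolution, propagates
    trueness-to-type codes, checks whether representatives are retraceable
    to measured samples, and reports per-position allele-variant
    frequencies. Includes a synthetic-collection generator with ground
    truth for validating every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    withr,
    igraph,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    readxl,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
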