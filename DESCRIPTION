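Package: driverlens
Title: Integrated Prioritization of Putative Cancer Driver Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nominates putative cancer driver genes in tumour cohorts that
    lack mutations in known cancer genes, by integrating per-sample
    expression calls from probe detection p-values, a consensus call of
    damaging mutations (truncating classes plus a two-of-three predictor
    vote for missense), a gene-length and recurrence correction, and four
    systems-level gene properties (network hub status, direct interaction
    with known cancer proteins, evolutionary origin, and duplicability).
    Also scores pooled shRNA silencing screens (log2 ratio of replicate
    means with top-probe collapse) and provides the group-comparison
    statistics used to contrast gene classes, together with a seeded
    synthetic-cohort generator with known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
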