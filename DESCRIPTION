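Package: bilenet
Title: Correlation and Correlation-Difference Networks for Bile Acid,
    Microbiome and Metatranscriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit for defined-community
    gnotobiotic studies that profile bile acids, 16S community composition
    and per-species metatranscriptomes across compartments (cecum, liver,
    serum). Provides internal-standard bile acid quantitation and class
    summaries, community diversity statistics (rarefaction, Shannon,
    Bray-Curtis, NMDS, ANOSIM), per-species differential expression with
    TMM normalization and permutation tests, all-pairs Spearman correlation
    networks with exact small-sample permutation p-values, and
    correlation-difference networks that identify feature pairs whose
    association changes between treatments. Includes a synthetic-data
    generator with planted effects so every stage is testable end to end.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
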