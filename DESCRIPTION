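Package: rbmgrn
Title: Gene Regulatory Network Inference with Paired Restricted Boltzmann Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores gene-gene interactions in expression matrices by training a
    bridged pair of single-layer restricted Boltzmann machines on every pair of
    genes, accepts pairs whose two interaction-strength values agree within a
    threshold, orients accepted edges with a two-way Gaussian naive-Bayes
    comparison, and assembles the result into directed weighted gene regulatory
    networks that can be compared across conditions (for example normal versus
    tumour samples). Includes MAXMIN per-gene normalization, Wilcoxon rank-sum
    gene ranking, a minimal GEO SOFT GDS reader, a synthetic expression
    generator with planted regulator-target pairs, and tidy/ggplot2 interfaces
    throughout.
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
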