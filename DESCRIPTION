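Package: raretaxa
Title: Abundant and Rare Taxa Dynamics in Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of amplicon OTU tables contrasting abundant and
    rare subcommunities: per-sample relative-abundance classification into six
    abundance categories, alpha and beta diversity with Bray-Curtis partitioning
    into balanced-variation and abundance-gradient components, time-lag
    regression of community turnover, ANOSIM, SIMPER, Mantel and indicator-value
    permutation tests, Sloan neutral community model fitting with occupancy
    confidence envelopes, and Spearman co-occurrence networks with Erdos-Renyi
    null ensembles, Louvain modules, Zi-Pi node roles and keystone detection.
    Includes Dirichlet-multinomial community simulators that provide ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
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
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
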