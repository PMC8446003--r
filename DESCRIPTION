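Package: balonet
Title: Sequence-Based Inference of Obligate Predator-Prey Interactions in
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers potential interactions between obligate bacterial
    predators (Bdellovibrio and like organisms) and their gram-negative prey
    from 16S rRNA OTU community time series. Provides abundance and taxonomy
    filtering of OTU tables, exhaustive negative Kendall rank-correlation
    screening with a hard tau/p gate, bipartite interaction-network assembly
    and topology analysis (degrees, Louvain modularity, path metrics),
    prey-range overlap and partitioning statistics, and supporting community
    statistics (alpha diversity, Bray-Curtis, PCoA, MRPP, rank-abundance
    Kolmogorov-Smirnov tests, environmental correlations). A generalized
    Lotka-Volterra community simulator with multinomial read sampling
    supplies ground-truth predation networks for validating edge recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    igraph,
    vegan,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
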