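Package: syncomcore
Title: Core Microbe Identification and Synthetic Community Design for Food Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies core microbes from time-series fermentation community
    and metabolite data using a three-criteria procedure (dominance,
    co-occurrence network hubness, volatile-compound association) followed by
    omission-experiment pruning; segments the fermentation timeline into
    phases by dynamic-programming changepoint detection on principal-component
    trajectories; assigns quality indicators to early or late phases; and
    encodes, enumerates and statistically compares temporal synthetic-community
    (SynCom) inoculation schedules. A synthetic-data generator with planted,
    recorded ground truth (core members, correlation cliques, producer links,
    changepoints) makes every stage of the pipeline testable end to end.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
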