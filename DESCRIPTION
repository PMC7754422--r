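Package: netreserve
Title: Optimal Sequencing of Conservation Interventions on Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deciding which social actors to engage, and in what
    order, to maximize the number of species protected when reserve and
    development behaviors spread over a social network. Provides an
    independent-cascade model of behavior spread over actor networks, a
    nestedness-controlled generator of species-by-site incidence matrices
    with the Brualdi-Sanderson discrepancy index and a checkerboard-swap
    null test, an exact factored Markov decision process planner solved by
    stochastic dynamic programming, and a value-of-information analysis
    comparing plans made with and without knowledge of the network,
    including a motif-by-nestedness-by-link-strength experiment grid and a
    small-scale fishery style case study.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
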