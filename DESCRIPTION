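Package: coopnet
Title: Evolution of Cooperation on Dynamic Social Networks with Social
    Inheritance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulator for the coevolution of cooperation and
    social network structure under a death-birth process with social
    inheritance of ties. Newborns always link to their parent, inherit each
    of the parent's connections with probability p_n, and link to each
    remaining individual with probability p_r. Payoffs follow a
    diluted-benefit cooperation game (total benefit divided among partners,
    optional synergy between connected cooperators, optional per-link
    maintenance costs) or a per-link prisoner's dilemma variant. Both the
    cooperation allele and the linking probabilities can be heritable and
    mutate, so network structure evolves jointly with behaviour. Provides
    tidy time-series output, replicate and parameter-grid orchestration,
    assortment observables, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    readr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
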