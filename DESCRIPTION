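Package: demesim
Title: Evolution of Cooperation in Deme-Structured Populations with Migration
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of the prisoner's dilemma in a population
    subdivided into demes connected by a migration network. Each generation
    individuals are randomly paired within their deme for one round of the
    game, accumulate fitness as a learning-weighted blend of past fitness and
    current payoff, migrate along the deme graph, and undergo local selection:
    elimination below a fitness threshold followed by restoration of the deme
    carrying capacity by least-fit culling or fitness-proportional expansion.
    An ensemble layer estimates cooperation-fixation and coexistence
    probabilities, compares migration topologies (random graph, island model,
    scale-free), sweeps the elimination threshold, and maps the four-regime
    phase diagram in the (migration rate, number of demes) plane including the
    critical deme number. Results are tidy tibbles with ggplot2 autoplot
    methods; a fast C++ engine and a reference R engine produce identical
    trajectories for any seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
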