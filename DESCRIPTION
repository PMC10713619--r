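Package: groupchase
Title: Agent-Based Group Chase and Escape with Strategy Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates predator-prey pursuit in a two-dimensional disk
    habitat where chasers use either a selfish direct chasing strategy or a
    cooperative group (encirclement) chasing strategy at a speed cost.
    Provides the full per-step update engine (hazard-avoiding targets,
    hunt/rest mode switching, same-species exclusion, capture and target
    replacement, spatial imitation learning), ensemble runners, and the
    observables used to study the resulting social dilemma: windowed hunting
    performance, set-resolved fitness of strategy compositions, Nash-arrow
    analysis, and strategy-fixation probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
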