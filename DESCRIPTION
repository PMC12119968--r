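Package: cldtools
Title: Aggregation and Consensus Analysis of Community-Built Causal Loop Diagrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing signed causal loop diagrams (CLDs) elicited in
    group model building workshops. Reads per-group edge lists, standardizes
    factor labels, enumerates and classifies feedback loops (reinforcing or
    balancing by the sign-product rule), aggregates groups into a union model
    with per-edge support, extracts a consensus core model around a focal
    problem variable, measures indirect-path consensus, and quantifies how
    proposed action ideas reach the core via signed pathways. Includes a
    synthetic multi-group CLD generator with known ground truth for edge-level
    recovery experiments, deterministic DOT/GraphML/JSON exports, and a
    reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
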