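Package: shiftnet
Title: Longitudinal Social Network Analysis of Shift-Based Team Communication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sociometric analysis of team communication collected
    shift by shift, as in emergency-department studies where every rostered
    clinician reports how often they initiated communication toward each named
    colleague on a 0 to 10+ scale across several relation types. Survey rows
    are abstracted into directed weighted matrices per shift and relation;
    dyadic network density, Freeman degree centralization and in-degree
    centrality are computed exactly as in the classic worked examples;
    association between relation networks is tested with the quadratic
    assignment procedure (QAP), a restricted permutation test that preserves
    the autocorrelational structure of network data; and results are
    stratified by week and day/night shift with boxplot summaries and
    sociogram export (GraphML/DOT). A seeded synthetic generator produces
    rosters and correlated multiplex communication networks with controllable
    density, degree heterogeneity, night-shift offset, inter-relation overlap
    and nonresponse, so the full pipeline is testable without access to raw
    survey data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
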