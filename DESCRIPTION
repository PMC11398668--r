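Package: wmnet
Title: Two-Area Spiking Network Model of Working-Memory Delay Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley) spiking network model of a
    sensory and an association cortical area performing a delayed
    match-to-sample working-memory task, together with the graph-structural
    analysis suite used to relate local circuit topology to the duration of
    delay-period activity: directed triad-motif census, recurrent-cycle and
    small-world measures, excitation-inhibition balance and hub statistics,
    Spearman correlation and ridge-regression feature attribution, and a
    spine-count-constrained prediction of per-region working-memory duration
    across 24 macaque cortical areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    igraph,
    deSolve,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
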