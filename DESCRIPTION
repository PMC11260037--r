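Package: matesim
Title: Mating Designs and Genomic Prediction in Simulated Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of livestock breeding
    programs to study how mate allocation affects genomic prediction. Simulates
    a historical population to mutation-drift equilibrium through a bottleneck,
    expands it, and runs a recent breeding population under five mating designs
    (random, positive and negative assortative, and simulated-annealing
    minimized or maximized inbreeding). Marker effects are estimated by
    ridge-regression BLUP (SNP-BLUP) from a multi-generation reference set and
    genomic breeding values are validated one generation forward. Reports
    prediction accuracy, bias of true on estimated breeding values, and
    linkage-disequilibrium r2 decay in distance bins, with replicate summaries
    and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
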