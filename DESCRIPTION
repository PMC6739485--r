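Package: spclone
Title: Single-Progenitor Clone Dynamics and Lineage-Tracing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation and analysis of clonal dynamics in
    squamous epithelia maintained by a single progenitor population.
    Provides an exact continuous-time Markov simulator of progenitor
    clones with configurable division-fate bias, perturbation response
    and density-feedback competition between genotypes; experiment
    presets emulating clonal lineage-tracing protocols (low-dose
    irradiation courses, antioxidant co-treatment, EdU pulse-chase);
    the standard lineage-tracing readouts (two-dimensional clone-size
    histograms and residual maps, geometric-median clone size,
    floating-clone fraction, basal-cell density, EdU cohort
    statistics); a two-sample two-dimensional Kolmogorov-Smirnov
    (Peacock) test with a permutation null; and a truncated
    master-equation solver used both as an exact oracle for the
    simulator and as a likelihood engine for recovering fate-bias
    parameters from clone tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
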