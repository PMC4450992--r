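Package: epiland
Title: Waddington Landscapes and Collective Cell-Fate Decision Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs a Waddington epigenetic landscape from single-cell
    expression profiles (PCA projection, angular cell-state coordinate,
    per-stage Gaussian mixtures and a Boltzmann pseudo-potential), and models
    developmental lineage bifurcations as auto-activation / mutual-inhibition
    gene circuits of either two transcription factors or two clusters of
    transcription factors. Includes phase-space and fixed-point analysis of
    the circuit ODEs, an annealed stochastic population simulation that
    quantifies robustness of lineage ratios under degradation-rate
    perturbations, stage-wise coexpression clustering, and a synthetic-data
    generator emulating single-cell qRT-PCR profiles of mouse preimplantation
    development.
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
    jsonlite,
    mclust,
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
    yaml
Config/testthat/edition: 3
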