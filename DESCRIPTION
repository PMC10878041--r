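Package: assemblage
Title: Community Assembly Process Inference for Microbial OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the ecological processes that assemble microbial
    communities from OTU count tables and phylogenies. Implements the
    rare/abundant taxon classification (always-rare, conditionally rare,
    moderate, dominant), Sloan's neutral community model fit with
    binomial/Poisson model competition, abundance-weighted beta-mean
    nearest taxon distance (betaMNTD) with its standardized effect size
    (betaNTI), the Bray-Curtis Raup-Crick null model (RCbray), and the
    five-way partition of pairwise comparisons into heterogeneous
    selection, homogeneous selection, dispersal limitation, homogenizing
    dispersal and undominated assembly. A neutral/selection/dispersal
    community simulator provides known-truth data for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    biomformat,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
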