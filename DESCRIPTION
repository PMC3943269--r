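Package: recwalk
Title: Multilevel-Spatial Analysis of Neighborhood Disparities in
    Recreational Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how residential environments shape
    recreational walking. Simulates georeferenced cohorts of individuals
    nested in contiguous neighborhoods, aggregates resident survey items
    into ecometric neighborhood scores with multilevel ordinal models,
    fits convolution (Besag-York-Mollie) logistic and cumulative-logit
    regressions by Markov chain Monte Carlo with both exchangeable and
    intrinsic conditional-autoregressive neighborhood effects, decomposes
    between-neighborhood variation into spatially structured and
    unstructured interquartile odds ratios, and quantifies overall
    environmental disparities with a quartiled risk score and bootstrap
    percentile intervals. Includes a five-step modelling pipeline with
    report and choropleth (GeoJSON) export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    coda,
    lme4,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
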