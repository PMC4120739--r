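Package: mixboost
Title: Boosted Regression Trees for Interaction Discovery in Exposure Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits stochastic gradient boosted regression-tree ensembles and
    screens them for two-way and higher-order interaction effects among many
    correlated exposures using the Friedman-Popescu H statistic with a
    parametric-bootstrap null distribution.  Includes fast recursion-based
    partial dependence, bootstrap grid tuning with the one-standard-error
    rule, repeated split-sample stability checks, a simulator for a
    correlated log-normal contaminant panel with a known interacting target
    function, and power benchmarks against product-term regression with
    FDR-controlled marginal screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
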