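Package: MCPModRand
Title: Randomization Tests and Penalized Estimation for Generalized
    MCP-Mod Dose Finding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Randomization-based inference for the generalized multiple
    comparison procedures and modeling (MCP-Mod) approach to Phase II
    dose-finding trials. Provides optimal multiple-contrast test statistics,
    maximum-likelihood and Firth-penalized logistic regression with exact
    linear-programming detection of complete and quasicomplete separation,
    samplers and exact reference-set combinatorics for complete
    randomization, the random allocation rule and the permuted block design,
    Monte-Carlo randomization tests (model-based and residual-based), and
    simulation harnesses for binary-endpoint operating characteristics and
    potential-outcomes studies with continuous endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    mvtnorm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
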