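Package: infodyn
Title: Information Dynamics in Multivariate Gaussian Processes via
    State-Space Models and Penalized Vector Autoregression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying directed information flow in networks of
    jointly Gaussian stochastic processes. Vector autoregressive (VAR) models
    are identified from multichannel time series by ordinary least squares or
    by LASSO regression with hold-out selection of the penalty weight, then
    converted to innovations-form state-space models from which partial
    variances of arbitrary submodels are obtained by solving discrete
    algebraic Riccati equations. These yield exact transfer entropy, joint
    and conditional transfer entropy, and the minimum-mutual-information
    partial information decomposition into unique, redundant and synergistic
    transfer. Includes surrogate-data (IAAFT) and sparsity-based significance
    tests for network reconstruction, simulation benchmarks with ground-truth
    networks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
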