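Package: heatmilk
Title: Heat-Stress Climate Indices and Sparse Regression Models for Milk Components
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes six bioclimatic heat-stress indices (THI, ETI, ESI,
    HLI, modified HLI, RRP) from daily meteorology, including the humidity
    chain (saturation vapour pressure, vapour pressure, relative humidity,
    dew point) and black-globe temperature. Links monthly index means to
    dairy milk components (yield, fat, protein) through multiple linear
    regression: candidate predictor subsets are enumerated along a LASSO
    regularization path solved by in-package cyclic coordinate descent,
    refit by ordinary least squares and scored with the Gaussian AIC, with
    an Occam tie-break among near-tied models. Validation tools provide
    leave-one-year-out cross-validation, mean-squared-error skill scores,
    root-mean-square prediction error, and Q-Q residual diagnostics, plus a
    stratified non-parametric bootstrap for uncertainty. A synthetic-data
    generator emulates multi-zone daily meteorology and milk responses so
    the whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
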