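Package: corrbound
Title: Random Correlation Matrices from Sequential Coefficient Bounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates valid random correlation matrices of any dimension by
    sequentially computing the exact theoretical bounds of each correlation
    coefficient from the hypersphere (correlative-angle) decomposition and
    drawing each coefficient from a bounded distribution within its bounds,
    followed by random reordering for exchangeability and an eigenvalue
    validity check. Includes exact transforms between correlative angles,
    the trigonometric Cholesky-type factor and correlation matrices,
    rejection-sampling and spectrum-based (Bendel-Davies type) baseline
    generators, and Monte-Carlo diagnostics for per-attempt validity rates
    and coefficient marginal distributions.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    jsonlite,
    yaml,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
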