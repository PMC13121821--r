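Package: irtstream
Title: Online Stochastic Newton Estimation for Item Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time online estimation of item and ability parameters in
    unidimensional (2PL) and multidimensional (M2PL) logistic item response
    models via truncated stochastic Newton recursions, with and without
    Polyak-Ruppert-style weighted iterate averaging (TSNA and TASNA).
    Marginal likelihoods are approximated on a fixed tensor-product
    Gauss-Hermite grid; abilities are scored online by expected a posteriori
    (EAP) estimation; standard errors come from the inverse accumulated
    Hessian. Includes a fixed-quadrature Bock-Aitkin EM baseline, a
    synthetic-data generator with Beguin-Glas anchor constraints, a
    bias/RMSE replication harness, and streaming CSV/JSONL input-output
    with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
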