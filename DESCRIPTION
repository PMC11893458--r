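Package: latentcircuit
Title: Latent Circuit Inference for Heterogeneous Neural Population Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits latent circuit models to neural population responses: a
    small rectified-linear recurrent circuit whose trajectories, embedded
    through an orthonormal map parameterized by the Cayley transform,
    reproduce high-dimensional responses together with behavioral outputs.
    Includes a testbed of Dale-constrained recurrent neural networks trained
    on a context-dependent decision-making task, the conjugation relations
    linking latent and ambient connectivity, rank-one connectivity
    perturbations and activity stimulation along embedding axes, ensemble
    fitting with solution-space clustering, a permutation test for the
    dependence of inferred connectivity on neural responses, and
    preprocessing plus synthetic surrogate generators for condition-averaged
    firing-rate data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    rlang,
    withr,
    yaml,
    mclust
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
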