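Package: btties
Title: Bayesian Bradley-Terry Models with Ties via Polya-Gamma Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalable Bayesian inference for the Bradley-Terry model with
    tied comparisons (the Rao-Kupper extension), designed for comparative
    judgement studies that rank small areas such as UK wards. A
    Polya-Gamma data augmentation scheme yields a conjugate Gibbs update
    for the latent quality parameters under any multivariate normal
    prior, including spatially correlated priors built from a ward
    adjacency graph via the normalised matrix exponential. The tie
    parameter takes a free choice of prior and is updated by
    Metropolis-Hastings. A random-walk Metropolis baseline sampler, a
    synthetic comparative-judgement data generator, effective-sample-size
    diagnostics and plotting are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    expm,
    ggplot2,
    Matrix,
    mvtnorm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse,
    withr
Config/testthat/edition: 3
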