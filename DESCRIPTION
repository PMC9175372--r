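Package: ppostrial
Title: Bayesian Two-Stage Phase II Trial Designs with Posterior Predictive
    Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and monitoring machinery for Bayesian single-arm
    two-stage phase II trials with a binary response endpoint, together
    with a randomized two-arm comparison and a synthetic trial simulator.
    Provides conjugate beta-binomial posterior inference, beta-binomial
    posterior predictive distributions, interim monitoring by the
    posterior predictive probability of success, an exhaustive search for
    Simon-type optimal and minimax two-stage designs with exact binomial
    operating characteristics, a log-odds-ratio posterior for a
    randomized comparison computed by deterministic quadrature, and a
    patient-level simulator with permuted-block randomization and
    correlated binary co-primary endpoints combined by an
    at-least-one-of responder rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    coda,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
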