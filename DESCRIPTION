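Package: decoyrace
Title: Distractor and Decoy Effects in Two-Attribute Risky Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modelling and analysis pipeline for distractor (decoy) effects in
    speeded risky choice between prospects defined by reward magnitude and
    probability. Provides analytic choice and response-time likelihoods for
    feedforward-inhibition race models and a dual-route (mutual inhibition
    plus divisive normalisation) model, context-dependent utility models
    (selective integration, adaptive gain, divisive normalisation), static
    softmax models with binomial likelihoods, maximum-likelihood fitting with
    multi-start optimisation and cross-validation, random-effects Bayesian
    model selection with protected exceedance probabilities, model and
    parameter recovery harnesses, weighted logistic regression analyses of
    relative choice accuracy, permutation-based condition-unspecific bias
    correction, quantile-window binned accuracy maps, and a synthetic-data
    generator emulating the ternary/binary matched trial design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
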