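Package: riskbn
Title: Hybrid Bayesian Networks for Passenger Collision-Risk Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how passengers of an automated vehicle perceive
    the risk of colliding with crossing pedestrians in a shared space.
    Provides a 2^(7-2) resolution-IV fractional factorial trial-plan builder,
    a synthetic-data generator for subjective risk-assessment traces and
    skin-conductance responses, trial-windowed indicator extraction (iSA,
    mSA, nSCR, mSCR), compound Poisson-gamma (Tweedie, 1 < p < 2) density
    evaluation and log-link regression with profile likelihood over the
    power parameter, exhaustive enumeration and BIC scoring of hybrid
    Gaussian/Tweedie Bayesian-network structures with Raftery evidence
    grading, and BIC-based clustering of condition-cell means by exact
    set-partition enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
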