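Package: statecue
Title: Brain-State Dynamics of Appetite During Naturalistic Food-Cue
    Viewing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decomposes parcellated BOLD time series into recurring brain
    states with a Gaussian-emission hidden Markov model, aligns state
    fractional occupancy with continuous appetite ratings through sliding
    windows, predicts windowed appetite with nested leave-one-subject-out
    ridge regression, derives per-subject state expression, and relates
    it to body mass index and food craving via BCa bootstrap mediation
    and to six-month BMI trajectories via average-linkage clustering.
    Ships a synthetic-cohort generator with planted ground truth so the
    full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
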