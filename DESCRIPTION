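Package: condiff
Title: Conflict Diffusion Models and Cued Attentional Suppression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of conflict diffusion models of selective
    attention -- the shrinking spotlight model (SSP) and the dual-stage
    two-phase model (DSTP) -- together with the full behavioural analysis
    stack for cued distractor-suppression experiments: trial-schedule
    construction for flanker-style visual search designs, response-time
    trimming and participant exclusion rules, congruency effects and
    conditional accuracy functions, quantile-binned G-squared model fitting
    with binned BIC model comparison, Bayesian random-intercept mixed models
    with interaction Bayes factors and HDI+ROPE equivalence decisions, a
    sequential Bayes-factor design controller, gaze area-of-interest
    occupancy, cue-association rating summaries, Cohen's kappa, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rjags,
    coda,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
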