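Package: panelsurv
Title: Simulating and Estimating Among-Strain Variance in Lifespan
    Response to Dietary Restriction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing genetic-reference-panel
    lifespan experiments that compare dietary restriction (DR) with ad
    libitum (AL) feeding across inbred strains. Simulates survival data
    from a Gompertz proportional-hazards model with Gaussian strain-level
    deviations in the diet effect, and estimates the among-strain
    standard deviation and coefficient of genetic variation (CV_G) on the
    mean-difference and log-hazard-ratio scales, by no-pooling
    (strain-stratified) and partial-pooling (mixed-model) analyses. The
    partial-pooling hazard-scale estimator is a mixed-effects Cox model
    fitted by penalized partial likelihood with a Laplace-approximated
    integrated likelihood. Replicated simulation studies summarise
    estimator bias, between-experiment replicability of strain effects,
    and power of the among-strain variance test, for use in study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    flexsurv,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
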