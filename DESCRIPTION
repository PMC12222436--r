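Package: cpuessm
Title: Hierarchical Bayesian State-Space Modelling of Multi-Taxon Fishery
    Catch-Per-Unit-Effort
Version: 0.1.0
Authors@R:
    person("SFCA", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates long-term relative-abundance trends of co-occurring
    fishery taxa from annual catch and shared effort records. A hierarchical
    Bayesian state-space model places latent log catch-per-unit-effort
    random walks with period-specific drift under a lognormal catch
    observation layer, models the shared effort series as a Poisson
    observation of a latent log random walk (accommodating missing years),
    and ties taxon-level growth-rate and temperature-anomaly coefficients
    together through a multivariate normal community prior. Includes a
    fully parameterised synthetic-data generator for the same generative
    model, a Gibbs sampler with forward-filter backward-sampling, Kalman
    smoothing utilities, convergence diagnostics, posterior growth-rate
    summaries, and an exploratory life-history trait comparison via linear
    mixed models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
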