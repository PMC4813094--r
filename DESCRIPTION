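Package: wastemap
Title: Bayesian Space-Time Mapping of Child Wasting Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based geostatistics of acute-malnutrition (wasting)
    prevalence from cluster survey data. Implements extended-BIC best-subset
    covariate selection for binomial regression, a finite-element SPDE
    approximation to (non-stationary) Matern Gaussian fields, separable
    space-time Gaussian Markov random fields with AR(2) dynamics and a
    period-4 seasonal component, Laplace (empirical Bayes) inference for the
    latent Gaussian binomial model with an MCMC verification oracle, gridded
    posterior prevalence prediction, WHO wasting-severity classification with
    population-weighted case counts by zone, and de-clustered hold-out
    validation. Includes a synthetic-data generator emulating the structure
    of seasonal nutrition surveys so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
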