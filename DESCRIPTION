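Package: r2slopes
Title: Marginal and Conditional R-Squared for Random Slopes Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Variance partitioning and R-squared statistics for generalized
    linear mixed models with random slopes. Computes observation-level
    random-effect variances as the diagonal of Z Sigma Z', the mean
    random-effect variance Tr(Z Sigma Z')/n, marginal and conditional
    R-squared on the latent scale, distribution-specific variances for
    Gaussian, Poisson and binomial families, and covariate-conditioned
    intraclass correlations (repeatability at a fixed covariate value).
    Includes a self-contained REML/ML fitter for Gaussian random-slopes
    linear mixed models with a single grouping factor, a seeded synthetic
    data generator with analytic true variance partitions, and canned
    balanced/unbalanced design experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
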