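Package: vplddm
Title: Hierarchical Drift-Diffusion Analysis of Effector Specificity in
    Perceptual Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying whether visual perceptual learning transfers
    across response effectors (hand versus eye). Provides signal-detection
    behavioral statistics (loglinear-corrected d-prime, Specificity Index,
    exact sign tests, paired t-tests with Hedges' g, two-way repeated-measures
    ANOVA with partial eta-squared), a four-parameter drift-diffusion model
    core (Wiener first-passage-time density via complementary small-time and
    large-time series, absorption probabilities, a path sampler with
    Brownian-bridge crossing detection), hierarchical Bayesian model fitting
    by adaptive Metropolis-within-Gibbs over a declarative model space,
    DIC-based model selection, Gelman-Rubin and Geweke convergence
    diagnostics, posterior predictive checks, posterior-overlap parameter
    comparisons, and a seeded simulator of multi-session training and transfer
    experiments with an untrained two-effector control group.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
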