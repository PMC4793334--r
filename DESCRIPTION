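Package: bandmove
Title: Bayesian Estimation of Migratory Movement Probabilities from Band Recoveries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian estimation of region-to-region movement
    probabilities for migratory waterfowl from band-recovery (ring-recovery)
    data. Implements preseason-banding / hunting-season-recovery record
    filtering, per-band-type recovery matrices, a binomial recovery model
    with Dirichlet movement priors and Beta priors on reporting and harvest
    rates, a Metropolis-within-Gibbs sampler with Gelman-Rubin convergence
    diagnostics, band-type weighting of posteriors, derived migratory
    connectivity summaries, and a synthetic-data generator with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, coda, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
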