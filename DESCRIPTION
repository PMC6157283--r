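Package: pediherit
Title: Bayesian Heritability Estimation in Extended Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of narrow-sense heritability from extended
    (multi-generation) pedigrees with a fully Bayesian linear mixed model
    (the "animal model").  Provides pedigree parsing and validation,
    recursive kinship-matrix construction, marginal-likelihood evaluation
    through a cached eigendecomposition of the additive relationship
    matrix, deterministic grid posteriors and a conjugate blocked Gibbs
    sampler for the variance components, posterior summaries of
    heritability (mode, mean, equal-tailed credible intervals), model
    selection via the deviance information criterion, methylation
    beta-to-M preprocessing, genome-wide per-site scans with shared
    eigendecompositions, and a synthetic-data generator for
    three-generation family studies with known simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
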