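# pediherit

Bayesian estimation of narrow-sense heritability (h²) in extended,
multi-generation pedigrees — for family studies of quantitative traits
such as blood lipids or genome-wide DNA methylation, where relatedness
spans three generations rather than just twin or parent–offspring
pairs, and where point estimates of a variance ratio are meaningless
without their uncertainty.

## The model

The package fits the *animal model*, a linear mixed model with a
per-individual additive genetic value:

    y_i | eta_i, sigma_e^2  ~  N(eta_i, sigma_e^2)
    eta_i = beta_0 + x_i' beta + u_i
    u | sigma_g^2           ~  N(0, 2 sigma_g^2 K)

with K the kinship matrix computed recursively from the pedigree,
age and gender as fixed effects, Gamma(1, 0.00005) priors on the
precisions of both variance components, and

    h^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2).

Inference is fully Bayesian and comes in two engines: a deterministic
grid posterior over the log variance components (the default — exact
quadrature of the often spike-and-slab-shaped posterior) and a
conjugate blocked Gibbs sampler in the eigenbasis of the relationship
matrix.  An equivalent reparameterized formulation with a fixed
nuisance observation variance (sigma_0² = 4.54e-5, i.e. log sigma_0² =
-10) exposes the full h² posterior directly.  Whether a trait has
nonzero heritability at all is decided by comparing the model against
its fixed-effects-only null with the deviance information criterion
(ΔDIC > 10).

For genome-wide methylation scans the package converts beta values to
M-values (M = log2(β/(1−β))), filters SNP-related probes, fits the
model pair at every CpG site with one shared kinship
eigendecomposition, and summarizes the genome-wide h² distribution
(selected-site median/IQR, with-zero-component median, cross-timepoint
correlation).  A first-class synthetic-data generator produces
three-generation families, covariates, phenotypes, and two-timepoint
methylomes with known truth, so every estimator is testable
closed-loop.

## Worked example

```r
library(pediherit)

cfg <- sim_config(n_families = 42, true_h2 = 0.5, seed = 42)
ped <- simulate_pedigree(cfg)     # 502 individuals, 42 families
kin <- kinship_matrix(ped)
sim <- simulate_phenotype(ped, cfg, kin)

fit <- fit_grid(sim$data, kin)
fit
#> <herit_fit> direct model, grid engine, n = 502
#>   h2: mode 0.341, mean 0.334, 95% CI [0.157, 0.518]
#>   DIC 1444.64 (pD 1.94)

null <- fit_null(sim$data)
dic_select(null$dic, fit$dic)
#> <selection_result> delta DIC = 24.83 (null 1469.47 - genetic 1444.64): nonzero h2 (> 10)
```

The simulated truth is h² = 0.5: the 95% credible interval [0.16,
0.52] covers it, the interval width is the honest message (variance
ratios are hard even at n ≈ 500), and ΔDIC ≈ 25 gives strong evidence
for a nonzero genetic component.  The fixed-effect posterior recovers
the generating age effect (0.0112 ± 0.0020 against a true 0.01).

A genome-scale analysis is a few lines more:

```r
cfg <- sim_config(n_families = 42, n_sites = 448, seed = 7)
sm  <- simulate_methylome(ped, cfg, kin)
scan <- scan_heritability(sm$m$pre, ped, sm$covariates)
summarize_scan(scan)
cross_timepoint(scan, scan_heritability(sm$m$post, ped, sm$covariates))
```

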