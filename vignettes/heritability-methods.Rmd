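---
title: "Bayesian heritability estimation in extended pedigrees: models and methods"
author: "pediherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian heritability estimation in extended pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pediherit)
```

## The model

`pediherit` estimates narrow-sense heritability — the proportion of
phenotypic variance attributable to additive genetic variance — from
extended pedigrees with the animal model, a linear mixed model in which
every individual carries an additive genetic value:

$$
y_i \mid \eta_i, \sigma_e^2 \sim N(\eta_i, \sigma_e^2), \qquad
\eta_i = \beta_0 + \boldsymbol{x}_i^\top \boldsymbol{\beta} + u_i,
\qquad
\boldsymbol{u} \mid \sigma_g^2 \sim N(\boldsymbol{0},\, 2\sigma_g^2 \boldsymbol{K}),
$$

where $\boldsymbol{K}$ is the kinship matrix derived from the pedigree,
$\sigma_g^2$ the additive genetic variance, $\sigma_e^2$ the residual
variance, and the fixed effects are an intercept plus age (years) and
gender (0/1).  Heritability is the variance ratio

$$
h^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2} \in [0, 1].
$$

The target applications are family studies of quantitative traits —
blood lipids, or DNA methylation M-values measured per CpG site across
the genome — where the full three-generation pedigree structure, not
just twin or parent–offspring pairs, carries the relatedness
information.

Inference is fully Bayesian: both variance components receive
Gamma(`precision_shape`, `precision_rate`) priors on their precisions
(default Gamma(1, 0.00005), the conventional weakly-informative choice
for latent Gaussian models), and fixed effects receive independent
$N(0, 1000^2)$ priors on the standardized covariate scale — vague but
proper, which keeps the marginal likelihood closed-form and the
posterior always well defined.  The package reports the full posterior
of $h^2$: its mode (the point estimate), mean, and equal-tailed 95%
credible interval.

## Kinship

`kinship_matrix()` implements the classical recursion over a
topological ordering of the pedigree: for individual $i$ with parents
$(f, m)$,

$$
\phi(i,i) = \tfrac12 + \tfrac12\,\phi(f, m), \qquad
\phi(i,j) = \tfrac12\bigl(\phi(f,j) + \phi(m,j)\bigr),
$$

with missing-parent terms equal to zero (a missing parent is treated as
a unique unrelated founder).  The additive relationship matrix entering
the model is $A = 2K$; its eigendecomposition is computed lazily and
cached on the kinship object, because it is the single expensive step
that everything downstream reuses.  Sex is carried but unused — the
model is autosomal only — and individuals present in a phenotype file
but absent from the pedigree are rejected rather than silently added as
founders, which is the safer behaviour for a variance-ratio estimand.
The test suite validates the recursion against textbook closed forms
and an independent gene-dropping Monte Carlo oracle.

## Likelihood evaluation

Integrating $\boldsymbol{\beta}$ and $\boldsymbol{u}$ analytically
gives the Gaussian marginal
$\boldsymbol{y} \sim N(\boldsymbol{0},\, \tau^2 XX^\top + \sigma_g^2 A + \sigma_e^2 I)$.
After rotating into the eigenbasis of $A$ the non-fixed part of the
covariance is diagonal, and the Woodbury identity reduces every
evaluation to $O(np^2)$ following a one-time $O(n^3)$
eigendecomposition.  The quadratic form is computed in residual form
(a sum of nonnegative terms) rather than by the direct Woodbury
subtraction, which would lose up to six digits to cancellation when the
vague fixed-effect prior dominates the covariance.

## Posterior computation

### Grid engine (default)

`fit_grid()` evaluates the joint posterior of
$(\log\sigma_g^2, \log\sigma_e^2)$ on a regular lattice (default
$161 \times 161$ over $[-12, 6]$) and normalizes by the trapezoid rule.
Two numerical choices matter:

* **Lattice resolution.**  At $n \approx 500$ the marginal posterior of
  $\log\sigma_e^2$ has standard deviation $\approx 0.1$; the default
  spacing of $0.1125$ keeps trapezoid aliasing negligible (a coarser
  81-point lattice produces visible quadrature wobble in the $h^2$
  mode).  On a square lattice the likelihood reductions factor over the
  $2m-1$ distinct values of
  $\log\sigma_e^2 - \log\sigma_g^2$, so the finer grid costs little;
  per-trait fits take well under a second and genome scans amortize the
  outcome-independent precomputation across all sites.
* **Grid range.**  If more than 1% of posterior mass lands on the
  outermost lattice ring, the fit is re-run once on a widened grid;
  remaining boundary mass is flagged (`"grid_boundary"`) rather than
  hidden.

The $h^2$ posterior follows by the change of variables
$h^2 = \operatorname{logit}^{-1}(\log\sigma_g^2 - \log\sigma_e^2)$:
the lattice masses are collapsed onto the difference, interpolated with
a monotone cubic in log density, and integrated on a fine grid.

**Point-estimate convention.**  The reported `h2_mode` is the argmax of
the marginal density on the internal logit scale, refined by a
three-point parabola and mapped back to $[0,1]$ (the mean and the
equal-tailed interval come from the same fine-grained distribution, and
a 512-bin $h^2$ density is returned for display).  The argmax is
deliberately *not* taken on the $h^2$ scale: the Gamma(1, 0.00005)
precision prior concentrates prior mass at very small variances, so
posteriors often carry a small spike near $\sigma_g^2 \approx 0$ (or,
with strong genetic signal, near $\sigma_e^2 \approx 0$, where $u$ can
absorb the residuals).  On the $h^2$ scale the Jacobian
$1/(h(1-h))$ inflates even a 2% boundary spike into the outermost bin,
collapsing the point estimate to 0.001 or 0.999 while the bulk of the
mass sits in a moderate slab.  The logit-scale argmax is invariant to
this artifact, matches how latent-Gaussian software reports
hyperparameter modes, and still returns $\approx 10^{-4}$ for traits
with truly zero heritability.

### Gibbs engine

`fit_gibbs()` is a conjugate blocked Gibbs sampler in the eigenbasis of
$A$: a joint Gaussian draw of the fixed effects (from their marginal
given the variances) and the rotated genetic values (conditionally
independent given $\boldsymbol{\beta}$), then inverse-gamma draws of
$\sigma_g^2$ and $\sigma_e^2$.  Eigenvalues below $10^{-8}$ are treated
as null directions, handling rank deficiency from duplicate founders.
Chains are reproducible given a mandatory seed; the effective sample
size of the $h^2$ draws is reported and flagged below 100.

*Known limitation:* with weak data the spike-and-slab posterior
geometry described above mixes slowly — the chain rarely crosses the
$\sigma_g^2 \approx 0$ spike — so grid and Gibbs estimates are only
expected to agree at informative sample sizes ($n \approx 500$ with
clear signal; cross-checked to within 0.02 in the tests).  The grid
engine, which integrates the bimodality exactly, is the default for
scans.

### Reparameterized formulation

`fit_reparameterized()` fixes the observation variance at a small
nuisance value $\sigma_0^2 = 4.54 \times 10^{-5}$
($\log \sigma_0^2 = -10$) and treats both $\boldsymbol{u}$ and the
residuals as latent effects.  This is the formulation in which the full
$h^2$ posterior is directly accessible as a function of two latent
variances while $\sigma_e^2$ stays identifiable; it must agree with the
direct formulation (mode difference $\le 0.02$ in the tests), and a
`sigma0_sq` large enough to absorb signal ($\ge 0.01\,\mathrm{var}(y)$)
triggers a warning.

## Model selection

Whether a trait has nonzero heritability is decided by comparing the
animal model against its fixed-effects-only null with the deviance
information criterion, computed on the marginal deviance with the
hyperparameters as the focus:
$D(\theta) = -2\log p(y \mid \theta)$,
$\mathrm{DIC} = 2\bar{D} - D(\bar\theta)$, with $\bar\theta$ the
posterior mean on the log-variance scale.  The genetic component is
selected when $\Delta\mathrm{DIC} = \mathrm{DIC}_{null} -
\mathrm{DIC}_{genetic}$ strictly exceeds 10, the conventional
strong-evidence cutoff.  Two caveats are documented rather than hidden:
$p_D$ can turn negative for bimodal posteriors (where $\bar\theta$
falls between modes), and the selection rule is conservative — in the
simulated study conditions it selects essentially no truly-zero sites,
about two thirds of sites at $h^2 = 0.3$, and virtually all sites at
$h^2 \ge 0.5$, consistent with a detection floor around
$h^2 \approx 0.1$–$0.15$ at $n \approx 500$.

## Methylation preprocessing

Genome-wide analyses operate on M-values,
$M = \log_2\bigl(\beta/(1-\beta)\bigr)$, computed from methylation
proportions with a clipping margin of $10^{-6}$ that prevents
infinities from rounded proportions (`beta_to_m()` /`m_to_beta()`).
`filter_snp_sites()` removes a user-supplied list of SNP-related CpG
probes; no default list is bundled, since published exclusion
catalogues differ by array and population.  Probe-type normalization
(eg beta-mixture quantile approaches) is out of scope: the synthetic
generator produces data that need none, and pre-normalized matrices
pass through unchanged.

## Genome scans

`scan_heritability()` fits the model pair per site with one shared
kinship eigendecomposition and one shared set of outcome-independent
grid quantities, so a 448-site scan over ~500 individuals completes in
seconds.  Per-site fits are stateless given that shared precomputation:
site order cannot affect results, per-site failures become flagged `NA`
rows instead of aborting, and with the grid engine the whole scan is
deterministic.  `summarize_scan()` reports the selected-site mean,
median and IQR of the $h^2$ modes plus the median over *all* sites
("with the zero component included" — non-selected sites contribute
their actual near-zero posterior modes, not literal zeros).
`cross_timepoint()` correlates per-site modes across two scans,
restricted to sites selected in both.

## The synthetic-data generator

Because family studies of this kind are rarely deposited, the package
carries a first-class generator whose defaults define the study
conditions used throughout the tests:

* **Pedigree template.**  Each family has two founder grandparent
  couples; each couple has Poisson(1)+1 children; one child of each
  couple forms the parent pair, whose Poisson(3)+1 children complete
  the third generation.  Families average ~12 members (roughly 10–16),
  and the template produces parent–offspring, full-sib, grandparental,
  avuncular and first-cousin kinships.  42 families ≈ 500 individuals, the
  sample size used for all calibration statements.
* **Covariates.**  Ages uniform within generation (grandparents 60–80,
  parents 35–55, children 10–30); gender taken from pedigree sex.
  Default effects $\beta_{age} = 0.01\sqrt{V}$ per year and
  $\beta_{gender} = 0.1\sqrt{V}$ (with $V$ the total variance) — small
  but nonzero so the covariate machinery is always exercised.
* **Phenotypes.**  $u$ drawn through the PSD-safe eigen square root of
  $2K$ (eigenvalues clipped at zero, not Cholesky, so rank-deficient
  relationship matrices work), $\sigma_g^2 = h^2 V$,
  $\sigma_e^2 = (1-h^2)V$; valid because $\mathrm{diag}(2K) = 1$ for
  non-inbred individuals, and a warning is raised otherwise.
* **Methylomes.**  Per site, $h^2 = 0$ with probability `pi0` (default
  0.05); otherwise $h^2 \sim \mathrm{Beta}(4, 8)$ — mode 0.3, right
  skewed, matching the zero-inflated right-skewed shape reported for
  genome-wide methylation heritability.  Site baselines follow a
  bimodal M-value mixture (peaks near $\pm 3$).  Two time points share
  the zero/nonzero labels; the nonzero values are coupled through a
  Gaussian copula with correlation `timepoint_correlation` (default
  0.7), and the standardized genetic draws are shared to the same
  degree, so uncoupled time points have uncorrelated estimation errors
  as well as uncorrelated truths.
* **Seeding.**  All randomness flows from one master seed through a
  deterministic hierarchy (master → family, master → site), so any
  family or site is reproducible in isolation.

What passing tests on these data do *not* show: the generator draws
from exactly the model being fitted, so estimator performance here is
an upper bound.  Real methylation data add probe-type chemistry
artifacts, batch effects, cell-type composition, shared-household
environmental covariance (whose omission inflates $h^2$), and
non-Gaussian residuals — none of which are simulated.

## Worked example

```{r example}
cfg <- sim_config(n_families = 42, true_h2 = 0.5, seed = 42)
ped <- simulate_pedigree(cfg)
kin <- kinship_matrix(ped)
sim <- simulate_phenotype(ped, cfg, kin)
fit <- fit_grid(sim$data, kin)
fit
null <- fit_null(sim$data)
dic_select(null$dic, fit$dic)
```

## Problem sizes and budgets

The simulation studies in the tests use 42 three-generation families
(~470–510 individuals), 50 replicates per operating point, and
448-site methylomes — a 1/1000-scale version of a 450K-array study —
chosen so the whole suite, including the closed-loop calibration
checks, runs in a few minutes on one core.  All reported calibration
statements (coverage of the 95% interval, mean absolute error of the
mode, selection rates, scan sensitivity/specificity) are recomputed at
these sizes by `scripts/acceptance.R`.

## Known limitations

* Autosomal additive model only: no dominance, epistasis,
  gene–environment interaction, X-linked or mitochondrial inheritance,
  and no special handling of monozygotic twins.
* No shared-environment component; family environmental covariance is
  absorbed into $\sigma_g^2$, biasing $h^2$ upward on real data.
* The Gamma(1, 0.00005) precision prior is mildly scale-informative
  (density $\propto e^{-\ell}$ on the log variance): exact scale
  equivariance of the posterior holds only in the weak-prior regime,
  and small prior-driven spikes at zero variance are part of the
  posterior, handled as described above.
* Gibbs mixing degrades on weak data (bimodal posteriors); use the grid
  engine there.
* Traits on wildly different scales than unit variance rely on the
  automatic grid widening; pre-scaling outcomes is recommended.
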