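# Synthetic-data generator: three-generation family pedigrees,
# covariates, phenotypes and methylome-like matrices drawn from the
# animal model itself, with the full simulation truth retained so that
# every estimator in the package can be tested closed-loop.
#
# All randomness flows from the single master seed in the config
# through a documented hierarchical scheme (master -> family for the
# pedigree, master -> site for per-site genetic and noise draws), so
# any family or site is reproducible in isolation.

#' Simulation configuration
#'
#' Bundles the generative truth for [simulate_pedigree()],
#' [simulate_phenotype()] and [simulate_methylome()].
#'
#' @param n_families number of independent families.
#' @param family_template `"three_generation_default"` (two founder
#'   grandparent couples, each with Poisson(1)+1 children; one child of
#'   each couple forms the parent pair; Poisson(3)+1 grandchildren --
#'   roughly 10-16 members) or `"full_sib_pairs"` (two founders plus
#'   two full sibs, 4 members).
#' @param true_h2 narrow-sense heritability of the simulated trait, in
#'   `[0, 1]`.
#' @param total_variance phenotypic variance
#'   `sigma_g^2 + sigma_e^2`; `sigma_g^2 = true_h2 * total_variance`
#'   (valid because `diag(2K) = 1` for non-inbred individuals).
#' @param beta0 intercept.
#' @param beta_age,beta_gender fixed-effect sizes (per year of age and
#'   for gender = 1); default to `0.01 * sqrt(total_variance)` and
#'   `0.1 * sqrt(total_variance)` -- small but nonzero so the covariate
#'   machinery is exercised.
#' @param zero_inflation_pi0 probability that a methylome site has
#'   truly zero heritability.
#' @param nonzero_h2_shape length-2 Beta shape parameters for the
#'   nonzero heritability component (default `c(4, 8)`: mode 0.3,
#'   right-skewed).
#' @param n_sites number of methylome sites.
#' @param timepoint_correlation Gaussian-copula correlation of the
#'   nonzero per-site heritabilities across the two time points (the
#'   zero/nonzero labels are shared).
#' @param seed master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 42L,
                       family_template = c("three_generation_default",
                                           "full_sib_pairs"),
                       true_h2 = 0.5, total_variance = 1,
                       beta0 = 0, beta_age = NULL, beta_gender = NULL,
                       zero_inflation_pi0 = 0.05,
                       nonzero_h2_shape = c(4, 8),
                       n_sites = 448L,
                       timepoint_correlation = 0.7,
                       seed = 1L) {
  family_template <- match.arg(family_template)
  if (is.null(beta_age)) beta_age <- 0.01 * sqrt(total_variance)
  if (is.null(beta_gender)) beta_gender <- 0.1 * sqrt(total_variance)
  stopifnot(n_families >= 1L, true_h2 >= 0, true_h2 <= 1,
            total_variance > 0,
            zero_inflation_pi0 >= 0, zero_inflation_pi0 <= 1,
            length(nonzero_h2_shape) == 2L, all(nonzero_h2_shape > 0),
            n_sites >= 1L,
            timepoint_correlation >= 0, timepoint_correlation <= 1)
  structure(list(n_families = as.integer(n_families),
                 family_template = family_template,
                 true_h2 = true_h2, total_variance = total_variance,
                 beta0 = beta0, beta_age = beta_age,
                 beta_gender = beta_gender,
                 zero_inflation_pi0 = zero_inflation_pi0,
                 nonzero_h2_shape = nonzero_h2_shape,
                 n_sites = as.integer(n_sites),
                 timepoint_correlation = timepoint_correlation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sim_family <- function(fid, template, seed) {
  set.seed(seed)
  id <- function(k) sprintf("%s_I%02d", fid, k)
  if (template == "full_sib_pairs") {
    df <- data.frame(
      id = id(1:4),
      father = c(NA, NA, id(1), id(1)),
      mother = c(NA, NA, id(2), id(2)),
      sex = c("male", "female", sample(c("male", "female"), 2L, replace = TRUE)),
      generation = c(1L, 1L, 2L, 2L),
      stringsAsFactors = FALSE)
    return(df)
  }
  nA <- stats::rpois(1L, 1) + 1L     # children of grandparent couple A
  nB <- stats::rpois(1L, 1) + 1L     # children of grandparent couple B
  nC <- stats::rpois(1L, 3) + 1L     # grandchildren
  k <- 0L
  nxt <- function() { k <<- k + 1L; id(k) }
  gpA <- c(nxt(), nxt()); gpB <- c(nxt(), nxt())
  chA <- replicate(nA, nxt()); chB <- replicate(nB, nxt())
  gc <- replicate(nC, nxt())
  data.frame(
    id = c(gpA, gpB, chA, chB, gc),
    father = c(NA, NA, NA, NA, rep(gpA[1L], nA), rep(gpB[1L], nB),
               rep(chA[1L], nC)),
    mother = c(NA, NA, NA, NA, rep(gpA[2L], nA), rep(gpB[2L], nB),
               rep(chB[1L], nC)),
    sex = c("male", "female", "male", "female",
            "male", if (nA > 1L) sample(c("male", "female"), nA - 1L,
                                        replace = TRUE),
            "female", if (nB > 1L) sample(c("male", "female"), nB - 1L,
                                          replace = TRUE),
            sample(c("male", "female"), nC, replace = TRUE)),
    generation = c(rep(1L, 4L), rep(2L, nA + nB), rep(3L, nC)),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-family pedigree
#'
#' Generates `n_families` independent families from the configured
#' template.  Deterministic given the config seed (per-family sub-seeds
#' are derived from it), and the result always satisfies
#' [validate_pedigree()].
#'
#' @param config a [sim_config()].
#' @return A [pedigree()] with an extra `"generation"` attribute
#'   (1 = grandparents/founders, 2 = parents, 3 = children) used by the
#'   covariate simulation.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fams <- lapply(seq_len(config$n_families), function(f)
    .sim_family(sprintf("F%03d", f), config$family_template,
                .derive_seed(config$seed, f)))
  df <- do.call(rbind, fams)
  fam_id <- sub("_I[0-9]+$", "", df$id)
  ped <- pedigree(fam_id, df$id, df$father, df$mother, df$sex)
  attr(ped, "generation") <- df$generation
  ped
}

# Ages by generation (grandparents 60-80, parents 35-55, children
# 10-30, uniform) and gender from the recorded pedigree sex.
.sim_covariates <- function(ped) {
  gen <- attr(ped, "generation")
  if (is.null(gen)) {
    depth <- integer(nrow(ped))
    fi <- match(ped$father, ped$id); mi <- match(ped$mother, ped$id)
    for (i in attr(ped, "topo_order")) {
      dp <- c(depth[fi[i]], depth[mi[i]], 0L)
      depth[i] <- max(dp, na.rm = TRUE) + 1L
    }
    gen <- pmin(depth, 3L)
  }
  lo <- c(60, 35, 10)[gen]
  age <- lo + stats::runif(nrow(ped)) * 20
  gender <- ifelse(ped$sex == "male", 0L,
                   ifelse(ped$sex == "female", 1L,
                          stats::rbinom(nrow(ped), 1L, 0.5)))
  data.frame(id = ped$id, age = age, gender = gender,
             stringsAsFactors = FALSE)
}

# Draw u ~ N(0, sg2 * A) through the PSD-safe eigen square root of A
# (eigenvalues clipped at zero rather than Cholesky, so rank-deficient
# relationship matrices from duplicate founders are handled).
.sim_genetic <- function(eig, sg2, z) {
  if (sg2 == 0) return(numeric(length(z)))
  drop(eig$vectors %*% (sqrt(pmax(eig$values, 0) * sg2) * z))
}

#' Simulate a phenotype on a pedigree
#'
#' Runs the animal model generatively: genetic values
#' `u ~ N(0, 2 sigma_g^2 K)` through the eigen square root of `2K`,
#' independent residuals, and age/gender fixed effects, with
#' `sigma_g^2 = true_h2 * total_variance` and
#' `sigma_e^2 = (1 - true_h2) * total_variance`.
#'
#' @param ped a [pedigree()].
#' @param config a [sim_config()].
#' @param kin optional precomputed [kinship_matrix()] of `ped` (pass it
#'   when simulating many replicates so the eigendecomposition is
#'   reused).
#' @return List with `data` (a [trait_data()] with age and gender
#'   covariates), `covariates` (data.frame `id`, `age`, `gender`) and
#'   `truth` (list: `u`, `sg2`, `se2`, `beta`, `h2`).  A warning is
#'   raised for inbred pedigrees, where `diag(2K) > 1` makes the
#'   realized heritability exceed the nominal one.
#' @export
simulate_phenotype <- function(ped, config, kin = NULL) {
  stopifnot(inherits(ped, "herit_pedigree"), inherits(config, "sim_config"))
  if (is.null(kin)) kin <- kinship_matrix(ped)
  eig <- .eigen_A(kin)
  n <- nrow(ped)
  set.seed(.derive_seed(config$seed, 500009L))
  if (any(abs(diag(2 * kin$values) - 1) > 1e-8))
    warning("pedigree contains inbred individuals; realized h2 differs ",
            "from the nominal true_h2")
  covar <- .sim_covariates(ped)
  sg2 <- config$true_h2 * config$total_variance
  se2 <- (1 - config$true_h2) * config$total_variance
  u <- .sim_genetic(eig, sg2, stats::rnorm(n))
  y <- config$beta0 + config$beta_age * covar$age +
    config$beta_gender * covar$gender + u +
    stats::rnorm(n, 0, sqrt(se2))
  list(data = trait_data(y, covar[, c("age", "gender")], ped$id),
       covariates = covar,
       truth = list(u = u, sg2 = sg2, se2 = se2,
                    beta = c(beta0 = config$beta0, age = config$beta_age,
                             gender = config$beta_gender),
                    h2 = config$true_h2))
}

#' Simulate a two-time-point methylome with known per-site heritability
#'
#' Per site, the true heritability is zero with probability
#' `zero_inflation_pi0` and otherwise Beta-distributed (the zero-inflated,
#' right-skewed mixture seen in genome-wide methylation heritability);
#' the zero/nonzero label is shared between the two time points and the
#' nonzero values are coupled through a Gaussian copula with the
#' configured correlation.  M-values are generated from the animal
#' model with site-specific baseline means (a bimodal mixture typical
#' of methylation arrays), shared standardized genetic draws across
#' time points (scaled by each time point's genetic variance), and
#' independent residual noise.
#'
#' @param ped a [pedigree()].
#' @param config a [sim_config()].
#' @param kin optional precomputed [kinship_matrix()].
#' @return List with `m` (list of two [methylation_matrix()] objects,
#'   `pre` and `post`, M scale), `covariates` (`id`, `age`, `gender`)
#'   and `truth` (data.frame: `site_id`, `h2_pre`, `h2_post`,
#'   `nonzero`).
#' @export
simulate_methylome <- function(ped, config, kin = NULL) {
  stopifnot(inherits(ped, "herit_pedigree"), inherits(config, "sim_config"))
  if (is.null(kin)) kin <- kinship_matrix(ped)
  eig <- .eigen_A(kin)
  n <- nrow(ped)
  S <- config$n_sites
  set.seed(.derive_seed(config$seed, 900001L))
  covar <- .sim_covariates(ped)
  zero <- stats::runif(S) < config$zero_inflation_pi0
  rho <- config$timepoint_correlation
  zs <- stats::rnorm(S)
  a <- config$nonzero_h2_shape[1L]; b <- config$nonzero_h2_shape[2L]
  h2_t <- function(zt) {
    q <- stats::pnorm(sqrt(rho) * zs + sqrt(1 - rho) * zt)
    ifelse(zero, 0, stats::qbeta(q, a, b))
  }
  h2_pre <- h2_t(stats::rnorm(S))
  h2_post <- h2_t(stats::rnorm(S))
  comp <- sample.int(3L, S, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mu <- stats::rnorm(S, mean = c(-3, 3, 0)[comp], sd = c(0.5, 0.5, 1)[comp])
  fx <- config$beta_age * covar$age + config$beta_gender * covar$gender
  tv <- config$total_variance
  make_tp <- function(h2s, tp_index) {
    vals <- matrix(0, S, n)
    for (s in seq_len(S)) {
      ## genetic draws are shared across time points to the same degree
      ## as the heritability truths: fully shared at correlation 1,
      ## independent at 0 (so uncoupled time points give uncorrelated
      ## estimation errors as well as uncorrelated truths)
      set.seed(.derive_seed(config$seed, 1000000L + s))
      zg_shared <- stats::rnorm(n)
      set.seed(.derive_seed(config$seed, 3000000L + tp_index * S + s))
      zg_own <- stats::rnorm(n)
      zg <- sqrt(rho) * zg_shared + sqrt(1 - rho) * zg_own
      set.seed(.derive_seed(config$seed, 2000000L + tp_index * S + s))
      eps <- stats::rnorm(n, 0, sqrt((1 - h2s[s]) * tv))
      vals[s, ] <- mu[s] + fx + .sim_genetic(eig, h2s[s] * tv, zg) + eps
    }
    methylation_matrix(vals, scale = "M",
                       site_ids = sprintf("cg%06d", seq_len(S)),
                       sample_ids = ped$id)
  }
  list(m = list(pre = make_tp(h2_pre, 1L), post = make_tp(h2_post, 2L)),
       covariates = covar,
       truth = data.frame(site_id = sprintf("cg%06d", seq_len(S)),
                          h2_pre = h2_pre, h2_post = h2_post,
                          nonzero = !zero, stringsAsFactors = FALSE))
}
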