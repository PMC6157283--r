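# Model fitting: deterministic grid posteriors and a conjugate blocked
# Gibbs sampler for the animal model, plus the null (no-genetics) and
# reparameterized (fixed nuisance observation variance) formulations.

.prep_fit <- function(data, K) {
  stopifnot(inherits(data, "trait_data"), inherits(K, "kinship_matrix"))
  if (!identical(data$ids, K$ids)) K <- subset_kinship(K, data$ids)
  eig <- .eigen_A(K)
  std <- .standardize_X(data$X)
  rot <- .rotate_data(data$y, std$X, eig)
  list(rot = rot, std = std, K = K)
}

# Normalized posterior weights on the grid: likelihood x Gamma priors on
# the precisions (log-variance scale, Jacobian included), trapezoid
# cell weights, and the boundary-mass diagnostic.
.grid_posterior <- function(ev, loglik, priors, null = FALSE) {
  lp <- loglik + .log_prior_logvar(ev$Le, priors)
  if (!null) lp <- lp + .log_prior_logvar(ev$Lg, priors)
  tw <- function(x) {
    u <- sort(unique(x))
    if (length(u) == 1L) return(rep(1, length(x)))
    w <- ifelse(x == u[1L] | x == u[length(u)], 0.5, 1)
    w
  }
  w <- exp(lp - max(lp)) * tw(ev$Le) * (if (null) 1 else tw(ev$Lg))
  w <- w / sum(w)
  edge <- ev$Le == min(ev$Le) | ev$Le == max(ev$Le)
  if (!null) edge <- edge | ev$Lg == min(ev$Lg) | ev$Lg == max(ev$Lg)
  boundary_ok <- length(unique(ev$Le)) > 2L
  list(w = w, boundary_mass = if (boundary_ok) sum(w[edge]) else 0)
}

# Posterior of h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2) from grid atoms.
# The grid induces atoms on the lattice of delta = log(sg2) - log(se2)
# = logit(h2); the delta-marginal is interpolated with a monotone cubic
# on the log scale and integrated on a fine delta grid.  The mode is
# the density argmax on the internal logit(h2) scale mapped back to
# [0, 1]: taking the argmax on the h2 scale instead would let the
# 1/(h(1-h)) Jacobian blow up small prior-driven boundary spikes into
# the outermost bins.  Mean and the equal-tailed 95% interval come from
# the fine cumulative distribution; a 512-bin h2 density is returned
# for display.
.h2_from_grid <- function(Lg, Le, w, nbin = 512L) {
  delta <- Lg - Le
  ud <- sort(unique(round(delta, 9)))
  md <- rowsum(w, group = round(delta, 9))[, 1L]
  md <- md[as.character(ud)]
  if (length(ud) == 1L) {
    h <- stats::plogis(ud)
    return(list(mode = h, mean = h, ci95 = c(h, h),
                density = data.frame(h2 = h, mass = 1)))
  }
  lf <- stats::splinefun(ud, log(md + 1e-300), method = "monoH.FC")
  xf <- seq(min(ud), max(ud), length.out = 4001L)
  mf <- exp(lf(xf) - max(lf(xf)))
  mf <- mf / sum(mf)
  hf <- stats::plogis(xf)
  h2_mean <- sum(mf * hf)
  cw <- cumsum(mf)
  qs <- vapply(c(0.025, 0.975), function(p) hf[which(cw >= p)[1L]], numeric(1))
  bins <- pmin(pmax(ceiling(hf * nbin), 1L), nbin)
  bm <- rowsum(mf, bins)
  mids <- (as.integer(rownames(bm)) - 0.5) / nbin
  dens <- data.frame(h2 = mids, mass = bm[, 1L])
  ## mode: lattice argmax of the delta-marginal refined by a 3-point
  ## parabola in log density, so the estimate is not quantized to the
  ## grid spacing of the log-variance lattice
  k <- which.max(md)
  dstar <- ud[k]
  if (k > 1L && k < length(ud)) {
    l <- log(md[(k - 1L):(k + 1L)] + 1e-300)
    curv <- l[1L] - 2 * l[2L] + l[3L]
    if (curv < 0) {
      off <- 0.5 * (l[1L] - l[3L]) / curv
      dstar <- dstar + max(-1, min(1, off)) * (ud[k + 1L] - ud[k])
    }
  }
  mode <- stats::plogis(dstar)
  list(mode = mode, mean = h2_mean, ci95 = qs, density = dens)
}

# Posterior summary of the fixed effects: Gaussian mixture over grid
# points (GLS mean/covariance at each point), mapped back to the
# original covariate scale.
.beta_from_grid <- function(ev, es, w, Tmat, terms) {
  p <- ev$p
  Mu <- matrix(0, ev$G, p)
  for (j in seq_len(p)) for (k in seq_len(p))
    Mu[, j] <- Mu[, j] + ev$tau2 * ev$Minv[, (j - 1L) * p + k] * es$B[, k]
  m1 <- colSums(w * Mu)
  E2 <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in seq_len(p))
    E2[j, k] <- sum(w * (ev$tau2 * ev$Minv[, (j - 1L) * p + k] +
                           Mu[, j] * Mu[, k]))
  C <- E2 - tcrossprod(m1)
  mo <- drop(Tmat %*% m1)
  Co <- Tmat %*% C %*% t(Tmat)
  data.frame(term = terms, mean = mo, sd = sqrt(pmax(diag(Co), 0)),
             row.names = NULL)
}

.dic_from_grid <- function(ev, loglik, w, rot, null = FALSE) {
  Dbar <- sum(w * (-2 * loglik))
  lg_bar <- if (null) -Inf else sum(w * ev$Lg)
  le_bar <- sum(w * ev$Le)
  D_at <- -2 * .loglik_point(lg_bar, le_bar, rot, ev$tau2, ev$offset)
  if (!is.finite(D_at)) stop("non-finite deviance at posterior mean")
  list(dic = 2 * Dbar - D_at, pD = Dbar - D_at,
       theta_bar = c(log_sg2 = lg_bar, log_se2 = le_bar))
}

.new_fit <- function(...) structure(list(...), class = "herit_fit")

# Build the grid evaluator for a given spec (shared across outcomes on
# the same samples -- the amortization that makes genome scans cheap).
.build_eval <- function(rot, priors, grid, offset = 0, null = FALSE) {
  lgv <- if (null) -Inf else seq(grid$lo, grid$hi, length.out = grid$n)
  lev <- seq(grid$lo, grid$hi, length.out = grid$n)
  .grid_eval_build(rot, lgv, lev, priors$fixed_effect_prior_sd^2, offset)
}

# Turn a per-outcome grid evaluation into a herit_fit.  Returns NULL
# when too much posterior mass sits on the grid edge and the caller has
# not yet widened the grid (the caller then retries once on a wider
# grid with `accept_boundary = TRUE`).
.assemble_grid_fit <- function(ev, es, rot, std, priors, grid,
                               formulation = "direct", null = FALSE,
                               accept_boundary = FALSE) {
  post <- .grid_posterior(ev, es$loglik, priors, null = null)
  if (post$boundary_mass > grid$boundary_tol && !accept_boundary)
    return(NULL)
  warnings <- character(0)
  if (post$boundary_mass > grid$boundary_tol) warnings <- "grid_boundary"
  w <- post$w
  h2 <- if (null) NULL else .h2_from_grid(ev$Lg, ev$Le, w)
  dic <- .dic_from_grid(ev, es$loglik, w, rot, null = null)
  beta <- .beta_from_grid(ev, es, w, std$Tmat, colnames(std$X))
  sg2_mean <- if (null) 0 else sum(w * exp(ev$Lg))
  .new_fit(
    formulation = formulation, engine = "grid", n = rot$n,
    h2_mode = if (null) NA_real_ else h2$mode,
    h2_mean = if (null) NA_real_ else h2$mean,
    h2_ci95 = if (null) c(NA_real_, NA_real_) else h2$ci95,
    h2_density = if (null) NULL else h2$density,
    beta_summary = beta,
    sigma_summary = list(sg2_mean = sg2_mean, se2_mean = sum(w * exp(ev$Le))),
    dic = dic$dic, pD = dic$pD, theta_bar = dic$theta_bar,
    sigma0_sq = NULL,
    posterior = list(lg = ev$Lg, le = ev$Le, w = w, loglik = es$loglik),
    boundary_mass = post$boundary_mass,
    warnings = warnings
  )
}

# Shared grid-fit engine.  `offset` is the fixed nuisance observation
# variance of the reparameterized formulation (0 for the direct model);
# `null = TRUE` drops the genetic component entirely.
.fit_grid_core <- function(rot, std, priors, grid, offset = 0,
                           formulation = "direct", null = FALSE) {
  ev <- .build_eval(rot, priors, grid, offset, null)
  es <- .grid_eval_site(ev, rot$yt)
  fit <- .assemble_grid_fit(ev, es, rot, std, priors, grid, formulation, null)
  if (is.null(fit)) {
    wider <- grid_spec(grid$lo - 6, grid$hi + 3, grid$n, grid$boundary_tol)
    ev <- .build_eval(rot, priors, wider, offset, null)
    es <- .grid_eval_site(ev, rot$yt)
    fit <- .assemble_grid_fit(ev, es, rot, std, priors, wider, formulation,
                              null, accept_boundary = TRUE)
  }
  if (offset > 0) fit$sigma0_sq <- offset
  fit
}

#' Fit the Bayesian animal model on a deterministic grid
#'
#' Evaluates the joint posterior of `(log sigma_g^2, log sigma_e^2)` --
#' marginal likelihood (fixed effects and genetic values integrated
#' analytically) times Gamma priors on the precisions -- on a regular
#' grid, normalized by the trapezoid rule.  The heritability posterior
#' follows by the change of variables `h2 = sigma_g^2 / (sigma_g^2 +
#' sigma_e^2)`; the reported point estimate is the posterior mode of the
#' marginal h2 density (on a 512-bin discretization), with the mean and
#' the equal-tailed 95% credible interval alongside.  DIC is computed
#' from the marginal deviance (see [dic()]).
#'
#' If more than `grid$boundary_tol` posterior mass falls on the edge of
#' the grid, the fit is automatically re-run once on a widened grid; a
#' `"grid_boundary"` warning flag is attached if mass remains.
#'
#' @param data a [trait_data()].
#' @param K a [kinship_matrix()] covering `data$ids`.
#' @param priors a [prior_spec()].
#' @param grid a [grid_spec()].
#' @return An object of class `herit_fit`.
#' @seealso [fit_gibbs()], [fit_null()], [fit_reparameterized()],
#'   [h2_summary()], [dic()]
#' @export
fit_grid <- function(data, K, priors = prior_spec(), grid = grid_spec()) {
  pr <- .prep_fit(data, K)
  fit <- .fit_grid_core(pr$rot, pr$std, priors, grid)
  if (stats::var(data$y) == 0) fit$warnings <- c(fit$warnings, "degenerate_variance")
  fit
}

#' Fit the null model (no genetic component)
#'
#' The fixed-effects-only counterpart of the animal model:
#' `y = X beta + e`, `e ~ N(0, sigma_e^2 I)`.  The posterior over
#' `log sigma_e^2` is evaluated on a 1-D grid with the same prior and
#' quadrature conventions as [fit_grid()].  No heritability is defined
#' for this formulation.  Any kinship argument is accepted and ignored,
#' so callers can pass the same argument list as for the genetic model.
#'
#' @param data a [trait_data()].
#' @param priors a [prior_spec()].
#' @param grid a [grid_spec()].
#' @param K ignored (present for call-site symmetry with [fit_grid()]).
#' @return An object of class `herit_fit` with `formulation = "null"`.
#' @export
fit_null <- function(data, priors = prior_spec(), grid = grid_spec(), K = NULL) {
  stopifnot(inherits(data, "trait_data"))
  std <- .standardize_X(data$X)
  rot <- .identity_rot(data$y, std$X)
  fit <- .fit_grid_core(rot, std, priors, grid, formulation = "null",
                        null = TRUE)
  if (stats::var(data$y) == 0) {
    warning("outcome has zero variance; residual-variance posterior is degenerate")
    fit$warnings <- c(fit$warnings, "degenerate_variance")
  }
  fit
}

#' Fit the reparameterized animal model
#'
#' Equivalent formulation in which the observation variance is fixed at
#' a small nuisance value `sigma0_sq` and both the genetic values and
#' the residuals enter as latent effects:
#' `y = X beta + u + e + e0`, `u ~ N(0, sigma_g^2 A)`,
#' `e ~ N(0, sigma_e^2 I)`, `e0 ~ N(0, sigma0_sq I)`.  This leaves the
#' full joint posterior of both latent variances (and hence the h2
#' posterior) directly accessible while keeping `sigma_e^2`
#' identifiable.  The default `sigma0_sq = 4.54e-5` corresponds to
#' `log(sigma0^2) = -10`.
#'
#' @param data a [trait_data()].
#' @param K a [kinship_matrix()] covering `data$ids`.
#' @param priors a [prior_spec()].
#' @param sigma0_sq fixed nuisance observation variance; must be small
#'   relative to `var(y)` (a warning flag `"sigma0_large"` is attached
#'   at `sigma0_sq >= 0.01 var(y)`).
#' @param engine `"grid"` (deterministic) or `"gibbs"`.
#' @param grid a [grid_spec()] (grid engine).
#' @param n_iter,burn_in,seed Gibbs engine settings, as in [fit_gibbs()].
#' @return An object of class `herit_fit` with
#'   `formulation = "reparameterized"`.
#' @export
fit_reparameterized <- function(data, K, priors = prior_spec(),
                                sigma0_sq = 4.54e-5,
                                engine = c("grid", "gibbs"),
                                grid = grid_spec(),
                                n_iter = 10000L, burn_in = 2000L,
                                seed = NULL) {
  engine <- match.arg(engine)
  stopifnot(sigma0_sq > 0)
  flag <- character(0)
  if (sigma0_sq >= 0.01 * stats::var(data$y)) {
    warning("sigma0_sq is not small relative to var(y); ",
            "the nuisance component will absorb signal")
    flag <- "sigma0_large"
  }
  fit <- if (engine == "grid") {
    pr <- .prep_fit(data, K)
    .fit_grid_core(pr$rot, pr$std, priors, grid, offset = sigma0_sq,
                   formulation = "reparameterized")
  } else {
    if (is.null(seed)) stop("Gibbs engine requires an explicit seed")
    .fit_gibbs_core(data, K, priors, n_iter, burn_in, seed,
                    offset = sigma0_sq, formulation = "reparameterized")
  }
  fit$sigma0_sq <- sigma0_sq
  fit$warnings <- c(fit$warnings, flag)
  fit
}

# Conjugate blocked Gibbs sampler in the eigenbasis of A: alternate a
# joint Gaussian draw of (beta, a) -- beta drawn from its marginal
# given the variances, then the rotated genetic values a, which are
# conditionally independent given beta -- with inverse-gamma draws of
# sigma_g^2 | a (quadratic form a' D^{-1} a via the eigenvalues) and
# sigma_e^2 | residuals.  Eigenvalues below 1e-8 are treated as null
# directions (their a is pinned at 0 and excluded from the quadratic
# form), which handles PSD rank deficiency from duplicate founders.
.fit_gibbs_core <- function(data, K, priors, n_iter, burn_in, seed,
                            offset = 0, formulation = "direct") {
  if (n_iter - burn_in < 2000L)
    stop("need at least 2000 retained iterations (n_iter - burn_in)")
  pr <- .prep_fit(data, K)
  rot <- pr$rot; std <- pr$std
  tau2 <- priors$fixed_effect_prior_sd^2
  n <- rot$n; p <- rot$p
  clip <- 1e-8
  pos <- rot$d > clip
  n_eff <- sum(pos)
  dpos <- rot$d[pos]
  a_sh <- priors$precision_shape; a_rt <- priors$precision_rate
  set.seed(seed)
  vy <- stats::var(data$y)
  if (vy <= 0) vy <- 1e-6
  sg2 <- se2 <- vy / 2
  a <- numeric(n)
  n_keep <- n_iter - burn_in
  keep_sg2 <- keep_se2 <- numeric(n_keep)
  keep_beta <- matrix(0, n_keep, p)
  for (it in seq_len(n_iter)) {
    v <- sg2 * rot$d + se2 + offset
    ## beta | y, variances (a and e integrated out)
    Pb <- crossprod(rot$Xt, rot$Xt / v) + diag(1 / tau2, p)
    Rb <- chol(Pb)
    rhs <- crossprod(rot$Xt, rot$yt / v)
    mb <- backsolve(Rb, backsolve(Rb, rhs, transpose = TRUE))
    beta <- drop(mb + backsolve(Rb, stats::rnorm(p)))
    r <- rot$yt - drop(rot$Xt %*% beta)
    if (offset == 0) {
      ## a | beta (independent components in the eigenbasis)
      prec_a <- 1 / (sg2 * dpos) + 1 / se2
      mu_a <- (r[pos] / se2) / prec_a
      a[pos] <- mu_a + stats::rnorm(n_eff) / sqrt(prec_a)
      eps <- r - a
    } else {
      ## joint (a_i, e_i) | beta with fixed observation variance
      s0 <- offset
      eps <- numeric(n)
      q11 <- 1 / (sg2 * dpos) + 1 / s0
      q22 <- 1 / se2 + 1 / s0
      q12 <- 1 / s0
      det <- q11 * q22 - q12^2
      rhs2 <- r[pos] / s0
      mu_a <- (q22 - q12) * rhs2 / det
      mu_e <- (q11 - q12) * rhs2 / det
      c_aa <- q22 / det; c_ee <- q11 / det; c_ae <- -q12 / det
      z1 <- stats::rnorm(n_eff); z2 <- stats::rnorm(n_eff)
      a[pos] <- mu_a + sqrt(c_aa) * z1
      eps[pos] <- mu_e + (c_ae / sqrt(c_aa)) * z1 +
        sqrt(pmax(c_ee - c_ae^2 / c_aa, 0)) * z2
      if (any(!pos)) {
        prec_e <- 1 / se2 + 1 / s0
        mu_e0 <- (r[!pos] / s0) / prec_e
        eps[!pos] <- mu_e0 + stats::rnorm(sum(!pos)) / sqrt(prec_e)
      }
    }
    ## variance components (conjugate inverse-gamma updates)
    qg <- sum(a[pos]^2 / dpos)
    sg2 <- 1 / stats::rgamma(1L, shape = a_sh + n_eff / 2, rate = a_rt + qg / 2)
    se2 <- 1 / stats::rgamma(1L, shape = a_sh + n / 2,
                             rate = a_rt + sum(eps^2) / 2)
    if (it > burn_in) {
      k <- it - burn_in
      keep_sg2[k] <- sg2; keep_se2[k] <- se2; keep_beta[k, ] <- beta
    }
  }
  h2 <- keep_sg2 / (keep_sg2 + keep_se2)
  ess <- .ess(h2)
  warnings <- if (ess < 100) "low_ess" else character(0)
  ## posterior mode from a kernel density of the h2 draws
  mode <- if (stats::var(h2) == 0) h2[1L] else {
    de <- stats::density(h2, from = 0, to = 1, n = 512L)
    de$x[which.max(de$y)]
  }
  ## DIC from the marginal deviance along a thinned trajectory
  thin <- unique(round(seq(1L, n_keep, length.out = min(500L, n_keep))))
  D <- vapply(thin, function(k)
    -2 * .loglik_point(log(keep_sg2[k]), log(keep_se2[k]), rot, tau2, offset),
    numeric(1))
  theta_bar <- c(log_sg2 = mean(log(keep_sg2)), log_se2 = mean(log(keep_se2)))
  D_at <- -2 * .loglik_point(theta_bar[1L], theta_bar[2L], rot, tau2, offset)
  Dbar <- mean(D)
  bmean <- drop(std$Tmat %*% colMeans(keep_beta))
  bcov <- std$Tmat %*% stats::cov(keep_beta) %*% t(std$Tmat)
  .new_fit(
    formulation = formulation, engine = "gibbs", n = n, seed = seed,
    h2_mode = mode, h2_mean = mean(h2),
    h2_ci95 = unname(stats::quantile(h2, c(0.025, 0.975))),
    h2_samples = h2, sg2_samples = keep_sg2, se2_samples = keep_se2,
    ess_h2 = ess,
    beta_summary = data.frame(term = colnames(std$X), mean = bmean,
                              sd = sqrt(pmax(diag(bcov), 0)),
                              row.names = NULL),
    sigma_summary = list(sg2_mean = mean(keep_sg2), se2_mean = mean(keep_se2)),
    dic = 2 * Dbar - D_at, pD = Dbar - D_at, theta_bar = theta_bar,
    sigma0_sq = if (offset > 0) offset else NULL,
    warnings = warnings
  )
}

#' Fit the Bayesian animal model by blocked Gibbs sampling
#'
#' Markov chain Monte Carlo alternative to [fit_grid()]: a conjugate
#' blocked Gibbs sampler in the eigenbasis of the additive relationship
#' matrix, alternating (i) a joint Gaussian draw of the fixed effects
#' and the rotated genetic values and (ii) inverse-gamma draws of the
#' two variance components.  Heritability draws are
#' `sigma_g^2 / (sigma_g^2 + sigma_e^2)` per retained iteration; the
#' point estimate is the kernel-density argmax of those draws.  Chains
#' are fully reproducible given `seed`.
#'
#' @param data a [trait_data()].
#' @param K a [kinship_matrix()] covering `data$ids`.
#' @param priors a [prior_spec()].
#' @param n_iter total iterations; at least 2000 must remain after
#'   `burn_in`.
#' @param burn_in discarded initial iterations.
#' @param seed mandatory RNG seed.
#' @return An object of class `herit_fit` with `engine = "gibbs"`,
#'   including the retained `h2_samples` and the effective sample size
#'   `ess_h2` (a `"low_ess"` warning flag is attached below 100).
#' @export
fit_gibbs <- function(data, K, priors = prior_spec(), n_iter = 10000L,
                      burn_in = 2000L, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for fit_gibbs")
  .fit_gibbs_core(data, K, priors, n_iter, burn_in, seed)
}

#' Posterior summary of heritability
#'
#' @param fit a `herit_fit` from any genetic-model engine.
#' @return List with `mode`, `mean` and `ci95` (equal-tailed 95%
#'   credible interval), all in `[0, 1]`.  Errors for null fits, where
#'   no heritability is defined.
#' @export
h2_summary <- function(fit) {
  stopifnot(inherits(fit, "herit_fit"))
  if (fit$formulation == "null")
    stop("h2 is not defined for the null model")
  list(mode = fit$h2_mode, mean = fit$h2_mean, ci95 = fit$h2_ci95)
}

#' @export
print.herit_fit <- function(x, ...) {
  cat(sprintf("<herit_fit> %s model, %s engine, n = %d\n",
              x$formulation, x$engine, x$n))
  if (x$formulation != "null")
    cat(sprintf("  h2: mode %.3f, mean %.3f, 95%% CI [%.3f, %.3f]\n",
                x$h2_mode, x$h2_mean, x$h2_ci95[1L], x$h2_ci95[2L]))
  cat(sprintf("  DIC %.2f (pD %.2f)\n", x$dic, x$pD))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}
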