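# Independent oracles used across the suite.

# Gene-dropping Monte Carlo estimate of the kinship matrix: simulate
# allele transmission down the pedigree (two unique alleles per founder
# or missing-parent slot, one allele inherited at random from each
# parent) and estimate phi(i, j) as the average proportion of
# identical-by-descent allele comparisons.  Returns the estimate and
# its Monte Carlo standard error per pair.
gene_drop_kinship <- function(ped, n_rep, seed) {
  set.seed(seed)
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  ord <- attr(ped, "topo_order")
  pat <- matrix(0L, n, n_rep)
  mat <- matrix(0L, n, n_rep)
  allele <- 0L
  for (i in ord) {
    if (is.na(fi[i])) {
      allele <- allele + 1L; pat[i, ] <- allele
    } else {
      pick <- stats::runif(n_rep) < 0.5
      pat[i, ] <- ifelse(pick, pat[fi[i], ], mat[fi[i], ])
    }
    if (is.na(mi[i])) {
      allele <- allele + 1L; mat[i, ] <- allele
    } else {
      pick <- stats::runif(n_rep) < 0.5
      mat[i, ] <- ifelse(pick, pat[mi[i], ], mat[mi[i], ])
    }
  }
  est <- se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- ((pat[i, ] == pat[j, ]) + (pat[i, ] == mat[j, ]) +
                (mat[i, ] == pat[j, ]) + (mat[i, ] == mat[j, ])) / 4
      est[i, j] <- est[j, i] <- mean(ibd)
      se[i, j] <- se[j, i] <- stats::sd(ibd) / sqrt(n_rep)
    }
  }
  list(est = est, se = se)
}

# Dense multivariate-normal evaluation of the marginal log-likelihood:
# builds the full n x n covariance tau^2 X X' + sg2 A + se2 I and uses
# a Cholesky log-density.  The O(n^3)-per-evaluation reference the fast
# eigendecomposition route must match.
dense_loglik <- function(data, K, log_sg2, log_se2, priors = prior_spec()) {
  Ks <- if (identical(data$ids, K$ids)) K else subset_kinship(K, data$ids)
  A <- relationship_matrix(Ks)
  Xs <- pediherit:::.standardize_X(data$X)$X
  n <- nrow(A)
  Sig <- priors$fixed_effect_prior_sd^2 * tcrossprod(Xs) +
    exp(log_sg2) * A + exp(log_se2) * diag(n)
  R <- chol(Sig)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) +
            sum(backsolve(R, data$y, transpose = TRUE)^2))
}

# Small hand-built pedigree covering the textbook relationships:
# grandparents g1 x g2 -> father f and aunt a; married-in mother m and
# m's other mate f2 give a maternal half sib h1; aunt a x spouse sp
# give cousin k1; f x m give sibs c1, c2.
relationship_pedigree <- function() {
  pedigree(
    family = "fam1",
    id     = c("g1", "g2", "m", "f2", "sp", "f", "a", "c1", "c2", "h1", "k1"),
    father = c(NA,   NA,   NA,  NA,   NA,   "g1", "g1", "f", "f", "f2", "sp"),
    mother = c(NA,   NA,   NA,  NA,   NA,   "g2", "g2", "m", "m", "m",  "a"),
    sex    = c("male", "female", "female", "male", "male",
               "male", "female", "male", "female", "male", "female")
  )
}

# Shared moderate-size simulated dataset (pedigree + kinship with a
# warm eigendecomposition), built once per test run.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_families = 42L, seed = 424242L)
      ped <- simulate_pedigree(cfg)
      kin <- kinship_matrix(ped)
      pediherit:::.eigen_A(kin)
      cache <<- list(cfg = cfg, ped = ped, kin = kin)
    }
    cache
  }
})
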