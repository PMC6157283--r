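test_that("pedigree simulation is deterministic and always valid", {
  cfg <- sim_config(n_families = 3L, seed = 601L)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  for (s in 1:20) {
    ped <- simulate_pedigree(sim_config(n_families = 2L, seed = s))
    expect_true(validate_pedigree(ped))
  }
})

test_that("the three-generation template has the documented family sizes", {
  cfg <- sim_config(n_families = 40L, seed = 602L)
  ped <- simulate_pedigree(cfg)
  sizes <- table(ped$family)
  expect_gte(min(sizes), 7)           # 4 gp + 2 parents + >= 1 child
  expect_gt(mean(sizes), 9)
  expect_lt(mean(sizes), 15)
  gen <- attr(ped, "generation")
  expect_setequal(unique(gen), 1:3)
  ## every grandchild's parents come one from each grandparental couple
  kids <- ped[gen == 3L, ]
  expect_true(all(!is.na(kids$father) & !is.na(kids$mother)))
})

test_that("the full-sib-pair template is exactly two founders plus two sibs", {
  cfg <- sim_config(n_families = 100L, family_template = "full_sib_pairs",
                    seed = 603L)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 400L)
  K <- kinship_matrix(ped)$values
  vals <- sort(unique(round(as.vector(K), 10)))
  expect_true(all(vals %in% c(0, 0.25, 0.5)))
})

test_that("null heritability yields purely environmental variation", {
  cfg <- sim_config(n_families = 42L, true_h2 = 0, seed = 604L)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_matrix(ped)
  sim <- simulate_phenotype(ped, cfg, kin)
  expect_true(all(sim$truth$u == 0))
  resid <- sim$data$y - sim$data$X %*% c(cfg$beta0, cfg$beta_age,
                                         cfg$beta_gender)
  expect_equal(stats::var(as.vector(resid)), cfg$total_variance,
               tolerance = 0.1)
})

test_that("full heritability makes relative correlations track 2K", {
  cfg <- sim_config(n_families = 42L, true_h2 = 1, seed = 605L)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_matrix(ped)
  sim <- simulate_phenotype(ped, cfg, kin)
  u <- sim$truth$u
  A <- relationship_matrix(kin)
  idx <- which(A == 0.5 & upper.tri(A), arr.ind = TRUE)  # PO / full sibs
  z <- u / sqrt(cfg$total_variance)
  expect_lt(abs(mean(z[idx[, 1]] * z[idx[, 2]]) - 0.5), 0.15)
  expect_equal(stats::var(u), cfg$total_variance, tolerance = 0.2)
})

test_that("cross-sib product moments recover the simulated heritability", {
  cfg0 <- sim_config(n_families = 42L, true_h2 = 0.5, seed = 606L)
  ped <- simulate_pedigree(cfg0)
  kin <- kinship_matrix(ped)
  A <- relationship_matrix(kin)
  idx <- which(A == 0.5 & upper.tri(A), arr.ind = TRUE)
  est <- numeric(50)
  for (r in 1:50) {
    cfg <- sim_config(n_families = 42L, true_h2 = 0.5, seed = 7000L + r)
    sim <- simulate_phenotype(ped, cfg, kin)
    resid <- sim$data$y - sim$data$X %*% c(cfg$beta0, cfg$beta_age,
                                           cfg$beta_gender)
    z <- as.vector(scale(resid))
    est[r] <- mean(z[idx[, 1]] * z[idx[, 2]]) / 0.5
  }
  expect_lte(abs(mean(est) - 0.5), 0.05)
})

test_that("methylome truth follows the configured mixture", {
  cfg <- sim_config(n_families = 4L, n_sites = 448L,
                    zero_inflation_pi0 = 0.05, seed = 607L)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_matrix(ped)
  sm <- simulate_methylome(ped, cfg, kin)
  tr <- sm$truth
  expect_equal(nrow(tr), 448L)
  expect_equal(mean(!tr$nonzero), 0.05, tolerance = 0.6)
  nz <- tr$h2_pre[tr$nonzero]
  skew <- mean((nz - mean(nz))^3) / stats::sd(nz)^3
  expect_gt(skew, 0)                      # right-skewed nonzero component
  expect_true(all(tr$h2_pre[!tr$nonzero] == 0))
  expect_true(all(tr$h2_post[!tr$nonzero] == 0))

  all_zero <- simulate_methylome(ped, sim_config(n_families = 4L,
                                                 n_sites = 30L,
                                                 zero_inflation_pi0 = 1,
                                                 seed = 608L), kin)
  expect_true(all(all_zero$truth$h2_pre == 0))

  lockstep <- simulate_methylome(ped, sim_config(n_families = 4L,
                                                 n_sites = 60L,
                                                 timepoint_correlation = 1,
                                                 seed = 609L), kin)
  expect_identical(lockstep$truth$h2_pre, lockstep$truth$h2_post)
})

test_that("generated datasets round-trip through the file writers", {
  cfg <- sim_config(n_families = 2L, n_sites = 5L, seed = 610L)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_matrix(ped)
  sm <- simulate_methylome(ped, cfg, kin)

  pf <- tempfile(fileext = ".fam")
  write_pedigree(ped, pf)
  expect_equal(as.data.frame(read_pedigree(pf)), as.data.frame(ped),
               ignore_attr = TRUE)

  mf <- tempfile(fileext = ".tsv")
  write_methylation(sm$m$pre, mf)
  back <- read_methylation(mf, scale = "M")
  expect_equal(back$values, sm$m$pre$values, tolerance = 1e-12)

  cf <- tempfile(fileext = ".tsv")
  write_phenotypes(sm$covariates, cf)
  cov_back <- read_phenotypes(cf)
  expect_equal(cov_back$id, sm$covariates$id)
  expect_equal(cov_back$age, sm$covariates$age, tolerance = 1e-9)
})

test_that("estimated heritability increases with the simulated truth", {
  ss <- shared_sim()
  h2_grid <- c(0, 0.2, 0.4, 0.6, 0.8)
  means <- vapply(h2_grid, function(h2) {
    modes <- vapply(1:10, function(r) {
      cfg <- sim_config(n_families = 42L, true_h2 = h2,
                        seed = 8000L + round(100 * h2) + r)
      sim <- simulate_phenotype(ss$ped, cfg, ss$kin)
      fit_grid(sim$data, ss$kin)$h2_mode
    }, numeric(1))
    mean(modes)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
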