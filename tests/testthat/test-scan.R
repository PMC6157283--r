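make_scan_input <- function(n_families = 12L, n_sites = 6L, seed = 501L,
                            ...) {
  cfg <- sim_config(n_families = n_families, n_sites = n_sites,
                    seed = seed, ...)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_matrix(ped)
  sm <- simulate_methylome(ped, cfg, kin)
  list(cfg = cfg, ped = ped, kin = kin, sm = sm)
}

test_that("a single-site scan reproduces the direct fit of that trait", {
  si <- make_scan_input(n_sites = 1L)
  sc <- scan_heritability(si$sm$m$pre, si$ped, si$sm$covariates)
  expect_equal(nrow(sc), 1L)
  covar <- si$sm$covariates
  dat <- trait_data(si$sm$m$pre$values[1L, ], covar[, c("age", "gender")],
                    covar$id)
  fg <- fit_grid(dat, si$kin)
  fn <- fit_null(dat)
  expect_equal(sc$h2_mode, fg$h2_mode)
  expect_equal(sc$h2_mean, fg$h2_mean)
  expect_equal(sc$ci_lo, fg$h2_ci95[1L])
  expect_equal(sc$dic_genetic, fg$dic)
  expect_equal(sc$dic_null, fn$dic)
})

test_that("grid scans are deterministic and site-order invariant", {
  si <- make_scan_input(n_sites = 6L)
  s1 <- scan_heritability(si$sm$m$pre, si$ped, si$sm$covariates, seed = 2L)
  s2 <- scan_heritability(si$sm$m$pre, si$ped, si$sm$covariates, seed = 7L)
  expect_identical(s1, s2)  # grid engine ignores the seed entirely
  perm <- c(4L, 1L, 6L, 3L, 2L, 5L)
  mp <- methylation_matrix(si$sm$m$pre$values[perm, ], scale = "M",
                           site_ids = si$sm$m$pre$site_ids[perm],
                           sample_ids = si$sm$m$pre$sample_ids)
  sp <- scan_heritability(mp, si$ped, si$sm$covariates)
  expect_equal(as.data.frame(sp), as.data.frame(s1[perm, ]),
               ignore_attr = TRUE)
})

test_that("the kinship eigendecomposition is computed once per scan", {
  si <- make_scan_input(n_sites = 5L)
  assign("..eig_calls", 0L, envir = globalenv())
  suppressMessages(trace(eigen,
                         tracer = quote(.GlobalEnv$..eig_calls <-
                                          .GlobalEnv$..eig_calls + 1L),
                         print = FALSE, where = baseenv()))
  on.exit({ suppressMessages(untrace(eigen, where = baseenv()))
            rm("..eig_calls", envir = globalenv()) }, add = TRUE)
  scan_heritability(si$sm$m$pre, si$ped, si$sm$covariates)
  expect_equal(get("..eig_calls", envir = globalenv()), 1L)
})

test_that("per-site failures are flagged without aborting the scan", {
  si <- make_scan_input(n_sites = 4L)
  vals <- si$sm$m$pre$values
  vals[2L, ] <- Inf
  m <- methylation_matrix(vals, scale = "M",
                          site_ids = si$sm$m$pre$site_ids,
                          sample_ids = si$sm$m$pre$sample_ids)
  sc <- scan_heritability(m, si$ped, si$sm$covariates)
  expect_equal(nrow(sc), 4L)
  expect_true(grepl("fit_failed", sc$warnings[2L]))
  expect_true(is.na(sc$h2_mode[2L]))
  expect_false(any(grepl("fit_failed", sc$warnings[-2L])))
})

test_that("samples absent from pedigree or covariates are rejected", {
  si <- make_scan_input(n_sites = 2L)
  m <- si$sm$m$pre
  bad <- methylation_matrix(m$values, scale = "M", site_ids = m$site_ids,
                            sample_ids = c("stranger",
                                           m$sample_ids[-1L]))
  expect_error(scan_heritability(bad, si$ped, si$sm$covariates),
               "not in the pedigree")
  expect_error(scan_heritability(m, si$ped,
                                 si$sm$covariates[-3L, ]),
               "covariates missing")
})

test_that("scan summaries follow their definitions", {
  rows <- data.frame(
    site_id = paste0("cg", 1:4),
    h2_mode = c(0.4, 0.4, 0.4, 0.4), h2_mean = 0.4,
    ci_lo = 0.2, ci_hi = 0.6, dic_null = 0, dic_genetic = -20,
    delta_dic = 20, selected = TRUE, warnings = "",
    stringsAsFactors = FALSE)
  s <- summarize_scan(rows)
  expect_equal(s$n_selected, 4L)
  expect_equal(s$median_selected, 0.4)
  expect_equal(s$iqr_selected, 0)

  rows2 <- rows
  rows2$selected <- c(TRUE, TRUE, FALSE, FALSE)
  rows2$h2_mode <- c(0.4, 0.4, 0.0, 0.0)
  s2 <- summarize_scan(rows2)
  expect_equal(s2$median_with_zero_component, 0.2)
  expect_equal(s2$median_selected, 0.4)

  rows3 <- rows
  rows3$selected <- FALSE
  s3 <- summarize_scan(rows3)
  expect_equal(s3$n_selected, 0L)
  expect_true(is.na(s3$median_selected))

  rows4 <- rows
  rows4$warnings <- c("", "grid_boundary", "", "")
  expect_equal(summarize_scan(rows4, exclude_flagged = TRUE)$n_sites, 3L)
})

test_that("cross-timepoint correlation uses sites selected in both scans", {
  rows <- data.frame(site_id = paste0("cg", 1:5),
                     h2_mode = c(0.1, 0.2, 0.3, 0.4, 0.5),
                     selected = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  ct <- cross_timepoint(rows, rows)
  expect_equal(ct$n_both, 4L)
  expect_equal(ct$pearson_r, 1)
  few <- rows; few$selected <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_error(cross_timepoint(rows, few), "fewer than 3")
})

test_that("timepoint coupling drives the correlation of scan estimates", {
  ## uncorrelated truth: estimate correlation stays near zero
  si0 <- make_scan_input(n_families = 16L, n_sites = 200L, seed = 560L,
                         timepoint_correlation = 0, zero_inflation_pi0 = 0.05)
  a0 <- scan_heritability(si0$sm$m$pre, si0$ped, si0$sm$covariates)
  b0 <- scan_heritability(si0$sm$m$post, si0$ped, si0$sm$covariates)
  ct0 <- cross_timepoint(a0, b0)
  expect_lte(abs(ct0$pearson_r), 0.15)
  ## strongly coupled truth: clearly positive correlation
  si1 <- make_scan_input(n_families = 16L, n_sites = 100L, seed = 561L,
                         timepoint_correlation = 0.9,
                         zero_inflation_pi0 = 0.05)
  a1 <- scan_heritability(si1$sm$m$pre, si1$ped, si1$sm$covariates)
  b1 <- scan_heritability(si1$sm$m$post, si1$ped, si1$sm$covariates)
  ct1 <- cross_timepoint(a1, b1)
  expect_gt(ct1$pearson_r, 0.3)
})
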