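# Genome-wide per-site heritability scan: one genetic/null model pair
# per CpG site, with the kinship eigendecomposition and the
# outcome-independent grid quantities computed once and shared across
# all sites.

#' Per-site heritability scan of a methylation matrix
#'
#' Fits, for every site, the animal model (methylation M-value as the
#' outcome, age and gender as fixed effects, the pedigree random
#' effect) and its null counterpart, and applies the Delta-DIC
#' selection rule.  The kinship eigendecomposition is computed once per
#' sample set and reused across sites; with the default grid engine the
#' whole scan is deterministic.  Per-site fits are stateless given the
#' shared precomputation, so site order does not affect any per-site
#' result.  A failing site is recorded as a row of `NA`s flagged
#' `"fit_failed"` rather than aborting the scan.
#'
#' @param m a [methylation_matrix()] on the M scale; its sample ids
#'   must all be present in the pedigree (samples absent from the
#'   pedigree are an error, never silently added).
#' @param ped a [pedigree()].
#' @param covariates data.frame with columns `id`, `age`, `gender`
#'   covering every sample of `m`.
#' @param engine `"grid"` (default, deterministic) or `"gibbs"` (per
#'   site seeds derived from `seed` and the site index).
#' @param priors a [prior_spec()].
#' @param grid a [grid_spec()] (grid engine).
#' @param seed master seed (used by the Gibbs engine only).
#' @param dic_threshold Delta-DIC selection threshold.
#' @param n_iter,burn_in Gibbs engine settings.
#' @return An object of class `herit_scan`: data.frame with one row per
#'   site and columns `site_id`, `h2_mode`, `h2_mean`, `ci_lo`,
#'   `ci_hi`, `dic_null`, `dic_genetic`, `delta_dic`, `selected`,
#'   `warnings` (semicolon-joined flags, empty when clean).
#' @seealso [summarize_scan()], [cross_timepoint()]
#' @export
scan_heritability <- function(m, ped, covariates, engine = c("grid", "gibbs"),
                              priors = prior_spec(), grid = grid_spec(),
                              seed = 1L, dic_threshold = 10,
                              n_iter = 10000L, burn_in = 2000L) {
  engine <- match.arg(engine)
  stopifnot(inherits(m, "methylation_matrix"))
  if (m$scale != "M") stop("scan expects M-values; apply beta_to_m() first")
  missing_ped <- setdiff(m$sample_ids, ped$id)
  if (length(missing_ped))
    stop("sample(s) not in the pedigree: ",
         paste(utils::head(missing_ped, 5L), collapse = ", "))
  covariates <- as.data.frame(covariates)
  stopifnot(all(c("id", "age", "gender") %in% names(covariates)))
  ci <- match(m$sample_ids, as.character(covariates$id))
  if (anyNA(ci))
    stop("covariates missing for sample(s): ",
         paste(utils::head(m$sample_ids[is.na(ci)], 5L), collapse = ", "))
  covar <- covariates[ci, c("age", "gender"), drop = FALSE]

  K <- subset_kinship(kinship_matrix(ped), m$sample_ids)
  template <- trait_data(m$values[1L, ], covar, m$sample_ids)
  if (!identical(template$ids, m$sample_ids))
    stop("covariates contain missing values for scanned samples")

  if (engine == "gibbs") {
    rows <- lapply(seq_along(m$site_ids), function(s) {
      .scan_site_gibbs(m, s, covar, K, priors, n_iter, burn_in,
                       .derive_seed(seed, s), dic_threshold)
    })
    return(.scan_result(do.call(rbind, rows)))
  }

  eig <- .eigen_A(K)
  std <- .standardize_X(template$X)
  rot0 <- .rotate_data(template$y, std$X, eig)
  ev_g <- .build_eval(rot0, priors, grid)
  ev_n <- .build_eval(rot0, priors, grid, null = TRUE)
  ## rotate every site at once (one dense multiply)
  Yt <- crossprod(eig$vectors, t(m$values))

  rows <- lapply(seq_along(m$site_ids), function(s) {
    out <- tryCatch({
      rot <- rot0
      rot$yt <- Yt[, s]
      gfit <- .assemble_grid_fit(ev_g, .grid_eval_site(ev_g, rot$yt),
                                 rot, std, priors, grid)
      if (is.null(gfit)) {
        dat <- trait_data(m$values[s, ], covar, m$sample_ids)
        gfit <- fit_grid(dat, K, priors, grid)
      }
      nfit <- .assemble_grid_fit(ev_n, .grid_eval_site(ev_n, rot$yt),
                                 rot, std, priors, grid, formulation = "null",
                                 null = TRUE, accept_boundary = TRUE)
      sel <- dic_select(nfit$dic, gfit$dic, dic_threshold)
      data.frame(site_id = m$site_ids[s],
                 h2_mode = gfit$h2_mode, h2_mean = gfit$h2_mean,
                 ci_lo = gfit$h2_ci95[1L], ci_hi = gfit$h2_ci95[2L],
                 dic_null = nfit$dic, dic_genetic = gfit$dic,
                 delta_dic = sel$delta_dic, selected = sel$selected,
                 warnings = paste(c(gfit$warnings, nfit$warnings),
                                  collapse = ";"),
                 stringsAsFactors = FALSE)
    }, error = function(e) .failed_site_row(m$site_ids[s], conditionMessage(e)))
    out
  })
  .scan_result(do.call(rbind, rows))
}

.failed_site_row <- function(site_id, msg) {
  data.frame(site_id = site_id, h2_mode = NA_real_, h2_mean = NA_real_,
             ci_lo = NA_real_, ci_hi = NA_real_, dic_null = NA_real_,
             dic_genetic = NA_real_, delta_dic = NA_real_, selected = FALSE,
             warnings = paste0("fit_failed:", msg), stringsAsFactors = FALSE)
}

.scan_site_gibbs <- function(m, s, covar, K, priors, n_iter, burn_in,
                             site_seed, dic_threshold) {
  tryCatch({
    dat <- trait_data(m$values[s, ], covar, m$sample_ids)
    gfit <- fit_gibbs(dat, K, priors, n_iter, burn_in, seed = site_seed)
    nfit <- fit_null(dat, priors)
    sel <- dic_select(nfit$dic, gfit$dic, dic_threshold)
    data.frame(site_id = m$site_ids[s],
               h2_mode = gfit$h2_mode, h2_mean = gfit$h2_mean,
               ci_lo = gfit$h2_ci95[1L], ci_hi = gfit$h2_ci95[2L],
               dic_null = nfit$dic, dic_genetic = gfit$dic,
               delta_dic = sel$delta_dic, selected = sel$selected,
               warnings = paste(c(gfit$warnings, nfit$warnings),
                                collapse = ";"),
               stringsAsFactors = FALSE)
  }, error = function(e) .failed_site_row(m$site_ids[s], conditionMessage(e)))
}

.scan_result <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("herit_scan", "data.frame")
  df
}

#' Genome-wide summary of a heritability scan
#'
#' Computes the headline quantities of a scan: the number and fraction
#' of sites selected by the Delta-DIC rule, mean/median/IQR of the
#' point estimates among selected sites, and the median over all sites
#' ("with the zero component included" -- non-selected sites contribute
#' their actual posterior modes, which sit near zero, not literal
#' zeros).
#'
#' @param results a `herit_scan` (or data.frame with the same columns).
#' @param exclude_flagged drop sites with warning flags before
#'   summarizing.
#' @return An object of class `scan_summary`: list with `n_sites`,
#'   `n_selected`, `mean_selected`, `median_selected`, `iqr_selected`
#'   (all `NA` when nothing is selected), `median_with_zero_component`,
#'   and `histogram` (counts of `h2_mode` on 50 equal bins of `[0, 1]`).
#' @export
summarize_scan <- function(results, exclude_flagged = FALSE) {
  stopifnot(nrow(results) > 0L)
  if (exclude_flagged) results <- results[results$warnings == "", , drop = FALSE]
  ok <- !is.na(results$h2_mode)
  results <- results[ok, , drop = FALSE]
  sel <- results$h2_mode[results$selected]
  nb <- 50L
  bins <- pmin(pmax(ceiling(results$h2_mode * nb), 1L), nb)
  hst <- list(mids = (seq_len(nb) - 0.5) / nb, counts = tabulate(bins, nb))
  structure(list(
    n_sites = nrow(results),
    n_selected = length(sel),
    mean_selected = if (length(sel)) mean(sel) else NA_real_,
    median_selected = if (length(sel)) stats::median(sel) else NA_real_,
    iqr_selected = if (length(sel)) stats::IQR(sel) else NA_real_,
    median_with_zero_component = stats::median(results$h2_mode),
    histogram = data.frame(mid = hst$mids, count = hst$counts)
  ), class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf("<scan_summary> %d sites, %d selected (%.1f%%)\n",
              x$n_sites, x$n_selected, 100 * x$n_selected / x$n_sites))
  cat(sprintf("  selected h2: mean %.3f, median %.3f, IQR %.3f\n",
              x$mean_selected, x$median_selected, x$iqr_selected))
  cat(sprintf("  median with zero component: %.4f\n",
              x$median_with_zero_component))
  invisible(x)
}

#' Correlation of heritability across two time points
#'
#' Restricts to the sites selected (Delta-DIC above threshold) in BOTH
#' scans and returns the Pearson correlation of their per-site
#' heritability modes.
#'
#' @param results_a,results_b `herit_scan` results sharing site ids.
#' @return List with `n_both` (sites selected in both) and `pearson_r`.
#'   Errors with fewer than 3 common selected sites.
#' @export
cross_timepoint <- function(results_a, results_b) {
  common <- merge(as.data.frame(results_a)[, c("site_id", "h2_mode", "selected")],
                  as.data.frame(results_b)[, c("site_id", "h2_mode", "selected")],
                  by = "site_id", suffixes = c("_a", "_b"))
  both <- common[common$selected_a & common$selected_b, , drop = FALSE]
  if (nrow(both) < 3L)
    stop("fewer than 3 sites selected in both scans (", nrow(both), ")")
  list(n_both = nrow(both),
       pearson_r = stats::cor(both$h2_mode_a, both$h2_mode_b))
}
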