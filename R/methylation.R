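# Methylation preprocessing: site-by-sample matrices on the beta or M
# scale, the logit-type beta-to-M transform, and SNP-related probe
# exclusion.

#' Construct a methylation matrix
#'
#' @param values numeric matrix, sites in rows, samples in columns.
#' @param scale `"beta"` (proportions, strictly inside (0, 1)) or
#'   `"M"` (log2 ratios, unbounded).
#' @param site_ids,sample_ids identifiers; default to the dimnames.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(values, scale = c("beta", "M"),
                               site_ids = rownames(values),
                               sample_ids = colnames(values)) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  stopifnot(length(site_ids) == nrow(values),
            length(sample_ids) == ncol(values),
            !anyDuplicated(site_ids), !anyDuplicated(sample_ids))
  if (anyNA(values)) stop("methylation values must not contain NA")
  if (scale == "beta" && (any(values <= 0) || any(values >= 1)))
    stop("beta values must lie strictly in (0, 1)")
  dimnames(values) <- list(site_ids, sample_ids)
  structure(list(site_ids = as.character(site_ids),
                 sample_ids = as.character(sample_ids),
                 values = values, scale = scale),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d sites x %d samples, %s scale\n",
              length(x$site_ids), length(x$sample_ids), x$scale))
  invisible(x)
}

#' Convert beta values to M-values
#'
#' Applies the standard logit-type transform
#' `M = log2(beta / (1 - beta))`, with beta clipped to
#' `[epsilon, 1 - epsilon]` so that rounded proportions at the scale
#' ends cannot produce infinities.  The transform is strictly monotone
#' and odd around `beta = 0.5`.
#'
#' @param beta a [methylation_matrix()] on the beta scale.
#' @param epsilon clipping margin.
#' @return A `methylation_matrix` on the M scale.
#' @seealso [m_to_beta()]
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(inherits(beta, "methylation_matrix"))
  if (beta$scale != "beta") stop("input is already on the M scale")
  b <- pmin(pmax(beta$values, epsilon), 1 - epsilon)
  methylation_matrix(log2(b / (1 - b)), scale = "M",
                     site_ids = beta$site_ids, sample_ids = beta$sample_ids)
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (2^M + 1)`.
#'
#' @param m a [methylation_matrix()] on the M scale.
#' @return A `methylation_matrix` on the beta scale.
#' @export
m_to_beta <- function(m) {
  stopifnot(inherits(m, "methylation_matrix"))
  if (m$scale != "M") stop("input is not on the M scale")
  e <- 2^m$values
  methylation_matrix(e / (e + 1), scale = "beta",
                     site_ids = m$site_ids, sample_ids = m$sample_ids)
}

#' Remove SNP-related CpG sites
#'
#' Drops the sites named in a user-supplied exclusion list (eg a
#' published catalogue of probes overlapping known single-nucleotide
#' polymorphisms).  Surviving sites keep their order; excluded and
#' unmatched counts are reported via `message()`.
#'
#' @param m a [methylation_matrix()].
#' @param exclusion_ids character vector of site ids to remove; ids not
#'   present in the matrix are ignored (with a logged count).
#' @return The filtered `methylation_matrix`.
#' @export
filter_snp_sites <- function(m, exclusion_ids) {
  stopifnot(inherits(m, "methylation_matrix"))
  exclusion_ids <- as.character(exclusion_ids)
  hit <- m$site_ids %in% exclusion_ids
  unmatched <- sum(!exclusion_ids %in% m$site_ids)
  message(sum(hit), " site(s) removed; ", unmatched,
          " exclusion id(s) not present in the matrix")
  if (all(hit)) warning("all sites removed by the exclusion list")
  methylation_matrix(m$values[!hit, , drop = FALSE], scale = m$scale,
                     site_ids = m$site_ids[!hit], sample_ids = m$sample_ids)
}

#' Read a methylation matrix from TSV
#'
#' Expects a header line, the first column holding site ids and the
#' remaining columns one sample each.  Gzip-compressed files are
#' accepted transparently.
#'
#' @param path input path.
#' @param scale `"beta"` or `"M"`.
#' @return A [methylation_matrix()].
#' @export
read_methylation <- function(path, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  methylation_matrix(as.matrix(tab[, -1L, drop = FALSE]), scale = scale,
                     site_ids = tab[[1L]], sample_ids = colnames(tab)[-1L])
}

#' Write a methylation matrix as TSV
#'
#' @param m a [methylation_matrix()].
#' @param path output path (first column `site_id`).
#' @return `path`, invisibly.
#' @export
write_methylation <- function(m, path) {
  df <- data.frame(site_id = m$site_ids, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
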