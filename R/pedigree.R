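#' Construct a pedigree object
#'
#' A pedigree is a set of individual records with optional father/mother
#' links.  Individuals with both parents missing are founders.  The
#' constructor validates the structure (unique ids, resolvable parent
#' links, acyclicity) and stores a topological ordering (parents before
#' offspring) that the kinship recursion relies on.
#'
#' @param family character vector of family identifiers.
#' @param id character vector of unique individual identifiers.
#' @param father,mother character vectors of parent identifiers; `NA`
#'   denotes a missing parent.  A missing parent is treated as a unique,
#'   unrelated founder.
#' @param sex factor or character, one of `"male"`, `"female"`,
#'   `"unknown"`.  Sex is carried for bookkeeping and covariate
#'   simulation but is not used in (autosomal) kinship computation.
#' @return An object of class `herit_pedigree`: a `data.frame` with
#'   columns `family`, `id`, `father`, `mother`, `sex` and an attribute
#'   `topo_order` (record indices, parents before offspring).
#' @seealso [read_pedigree()], [kinship_matrix()], [validate_pedigree()]
#' @export
pedigree <- function(family, id, father, mother, sex = "unknown") {
  n <- length(id)
  sex <- rep_len(as.character(sex), n)
  ped <- data.frame(
    family = as.character(family),
    id     = as.character(id),
    father = as.character(father),
    mother = as.character(mother),
    sex    = sex,
    stringsAsFactors = FALSE
  )
  ped$father[!is.na(ped$father) & ped$father %in% c("0", "")] <- NA_character_
  ped$mother[!is.na(ped$mother) & ped$mother %in% c("0", "")] <- NA_character_
  bad_sex <- !ped$sex %in% c("male", "female", "unknown")
  if (any(bad_sex))
    stop("invalid sex value(s): ", paste(unique(ped$sex[bad_sex]), collapse = ", "))
  class(ped) <- c("herit_pedigree", "data.frame")
  validate_pedigree(ped)
  attr(ped, "topo_order") <- .topo_order(ped)
  ped
}

#' Validate a pedigree
#'
#' Checks the structural invariants: individual ids are unique, every
#' non-missing parent id refers to an individual in the pedigree, and
#' the parent graph is acyclic (no individual is its own ancestor).
#'
#' @param ped a [pedigree()] object (or a data.frame with the same
#'   columns).
#' @return `TRUE`, invisibly.  Violations raise errors that name the
#'   offending ids.
#' @export
validate_pedigree <- function(ped) {
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup))
    stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "))
  for (col in c("father", "mother")) {
    p <- ped[[col]]
    missing_ref <- !is.na(p) & !(p %in% ped$id)
    if (any(missing_ref))
      stop("unknown ", col, " id(s): ",
           paste(unique(p[missing_ref]), collapse = ", "))
  }
  .topo_order(ped)  # raises on cycles
  invisible(TRUE)
}

# Kahn's algorithm on the parent->offspring DAG.  Returns record indices
# such that both parents of record i appear before i.  Errors listing
# the individuals on a cycle if no complete ordering exists.
.topo_order <- function(ped) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  indeg <- (!is.na(fi)) + (!is.na(mi))
  # children[[j]] = records having j as a parent
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(fi[i])) children[[fi[i]]] <- c(children[[fi[i]]], i)
    if (!is.na(mi[i])) children[[mi[i]]] <- c(children[[mi[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (j in children[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) queue <- c(queue, j)
    }
  }
  if (length(ord) < n) {
    cyc <- setdiff(seq_len(n), ord)
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[cyc], collapse = ", "))
  }
  ord
}

#' Read a pedigree file
#'
#' Reads LINKAGE/PLINK-style pedigree text (columns FID IID PAT MAT SEX,
#' whitespace separated, no header, `"0"` = missing parent, sex coded
#' 1 = male, 2 = female, other = unknown) or a headed CSV with columns
#' `family,individual,father,mother,sex` (sex spelled out).
#'
#' @param path path to the pedigree file.
#' @param dialect `"linkage"` (default, .fam convention) or `"csv"`.
#' @return A validated [pedigree()] with records in file order.
#' @export
read_pedigree <- function(path, dialect = c("linkage", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (dialect == "linkage") {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 5L)
      stop("linkage pedigree needs at least 5 columns (FID IID PAT MAT SEX)")
    sex <- c("1" = "male", "2" = "female")[tab[[5L]]]
    sex[is.na(sex)] <- "unknown"
    pedigree(tab[[1L]], tab[[2L]], tab[[3L]], tab[[4L]], sex)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("family", "individual", "father", "mother", "sex")
    if (!all(need %in% names(tab)))
      stop("csv pedigree needs columns: ", paste(need, collapse = ", "))
    pedigree(tab$family, tab$individual, tab$father, tab$mother, tab$sex)
  }
}

#' Write a pedigree in LINKAGE/PLINK .fam layout
#'
#' @param ped a [pedigree()].
#' @param path output path.  Missing parents are written as `"0"`, sex as
#'   1/2/0 for male/female/unknown.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out <- data.frame(ped$family, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    sex)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.herit_pedigree <- function(x, ...) {
  founders <- is.na(x$father) & is.na(x$mother)
  cat(sprintf("<pedigree> %d individuals, %d famil%s, %d founders\n",
              nrow(x), length(unique(x$family)),
              if (length(unique(x$family)) == 1L) "y" else "ies",
              sum(founders)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Kinship matrix of a pedigree
#'
#' Computes the matrix of kinship coefficients phi(i, j) -- the
#' probability that an allele drawn at random from i and one from j are
#' identical by descent -- by the standard recursion over a topological
#' ordering: for individual i with parents (f, m),
#' phi(i, i) = 1/2 + phi(f, m)/2 and, for any j already processed,
#' phi(i, j) = (phi(f, j) + phi(m, j)) / 2, terms for missing parents
#' being zero.  Founders of different families are unrelated.
#'
#' The additive relationship matrix used in the animal model's
#' random-effect covariance is `A = 2 K` (see [relationship_matrix()]);
#' its eigendecomposition is computed lazily and cached on the object.
#'
#' @param ped a [pedigree()].
#' @return An object of class `kinship_matrix`: list with `ids` (row
#'   order matches the pedigree record order) and `values` (dense
#'   symmetric matrix of phi in `[0, 1]`, diagonal >= 1/2).
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "herit_pedigree"))
  n <- nrow(ped)
  ord <- attr(ped, "topo_order")
  if (is.null(ord)) ord <- .topo_order(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  K <- matrix(0, n, n)
  done <- logical(n)
  prev <- integer(0)
  for (i in ord) {
    f <- fi[i]; m <- mi[i]
    if (length(prev)) {
      kf <- if (!is.na(f)) K[f, prev] else 0
      km <- if (!is.na(m)) K[m, prev] else 0
      v <- 0.5 * (kf + km)
      K[i, prev] <- v
      K[prev, i] <- v
    }
    K[i, i] <- 0.5 + 0.5 * (if (!is.na(f) && !is.na(m)) K[f, m] else 0)
    done[i] <- TRUE
    prev <- c(prev, i)
  }
  dimnames(K) <- list(ped$id, ped$id)
  .new_kinship(ped$id, K)
}

.new_kinship <- function(ids, values) {
  structure(list(ids = ids, values = values, cache = new.env(parent = emptyenv())),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d x %d, mean off-diagonal phi = %.4g\n",
              length(x$ids), length(x$ids),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Additive relationship matrix
#'
#' Returns `A = 2 K`, the additive (numerator) relationship matrix that
#' scales the genetic random-effect covariance `sigma_g^2 * A`.  For
#' non-inbred individuals `diag(A) = 1`.
#'
#' @param K a [kinship_matrix()].
#' @return A dense symmetric matrix with dimnames from `K$ids`.
#' @export
relationship_matrix <- function(K) {
  stopifnot(inherits(K, "kinship_matrix"))
  2 * K$values
}

#' Restrict a kinship matrix to a sample subset
#'
#' Extracts the principal submatrix for the requested ids, in the
#' requested order.  The eigendecomposition cache of the parent matrix
#' is not carried over (it would be invalid for the subset).
#'
#' @param K a [kinship_matrix()].
#' @param ids character vector, a subset of `K$ids` in any order.
#' @return A new `kinship_matrix` over `ids`.
#' @export
subset_kinship <- function(K, ids) {
  stopifnot(inherits(K, "kinship_matrix"))
  idx <- match(ids, K$ids)
  if (anyNA(idx))
    stop("id(s) not present in kinship matrix: ",
         paste(ids[is.na(idx)], collapse = ", "))
  .new_kinship(ids, K$values[idx, idx, drop = FALSE])
}

# Cached eigendecomposition of A = 2K.  `cache$n_eigen` counts how many
# decompositions were actually performed (scans assert it stays at one
# per sample subset).
.eigen_A <- function(K) {
  if (is.null(K$cache$eig)) {
    K$cache$eig <- eigen(2 * K$values, symmetric = TRUE)
    K$cache$n_eigen <- (if (is.null(K$cache$n_eigen)) 0L else K$cache$n_eigen) + 1L
  }
  K$cache$eig
}

#' Export a kinship matrix as dense TSV
#'
#' @param K a [kinship_matrix()].
#' @param path output path; first column `id`, remaining columns one per
#'   individual.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(id = K$ids, K$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
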