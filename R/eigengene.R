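#' Standardize the rows of a module profile matrix
#'
#' Each gene row is centered to mean 0 and scaled to variance 1 (sample
#' variance, n-1 denominator). Constant rows cannot be standardized and are
#' dropped with a warning; if every row is constant this is an error.
#'
#' @param Y Gene-by-sample numeric matrix.
#' @return The standardized matrix (possibly with fewer rows).
#' @export
standardize_rows <- function(Y) {
  stopifnot(is.matrix(Y), is.numeric(Y))
  sds <- apply(Y, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (all(const)) stop("all rows are constant; nothing to standardize")
  if (any(const)) {
    warning("dropping ", sum(const), " constant row(s)")
    Y <- Y[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  (Y - rowMeans(Y)) / sds
}

#' Module eigengene via singular value decomposition
#'
#' The eigengene is the first right-singular vector of the row-standardized
#' module profile \eqn{Y = UDV^T}; it is a unit-norm summary profile over
#' the samples. Its sign is fixed so that the mean correlation between the
#' eigengene and the module's gene profiles is nonnegative. The proportion
#' of variance it explains is \eqn{d_1^2 / \sum_j d_j^2}.
#'
#' @param Y Row-standardized gene-by-sample matrix (at least one row, two
#'   columns); see [standardize_rows()].
#' @return Object of class `Eigengene`: list with `values` (unit-norm
#'   length-m vector, named by sample), `var_explained`, `n_genes`.
#' @export
compute_eigengene <- function(Y) {
  stopifnot(is.matrix(Y), is.numeric(Y))
  if (nrow(Y) < 1 || ncol(Y) < 2) stop("need >= 1 gene and >= 2 samples")
  s <- svd(Y)
  if (s$d[1] <= 0) stop("rank-0 matrix has no eigengene")
  v <- s$v[, 1]
  cors <- suppressWarnings(stats::cor(t(Y), v))
  msign <- mean(cors, na.rm = TRUE)
  if (is.finite(msign) && msign < 0) v <- -v
  names(v) <- colnames(Y)
  structure(list(values = v, var_explained = s$d[1]^2 / sum(s$d^2),
                 n_genes = nrow(Y)),
            class = "Eigengene")
}

#' @export
print.Eigengene <- function(x, ...) {
  cat("Eigengene over", length(x$values), "samples;",
      x$n_genes, "genes; var explained",
      format(x$var_explained, digits = 4), "\n")
  invisible(x)
}

#' Eigengenes for every module of an assignment
#'
#' Computes one eigengene per module from the tumor-sample profiles of an
#' omics layer (regression and survival downstream operate on tumor
#' profiles; set `tumor_only = FALSE` to use all samples).
#'
#' @param omics An [omics_matrix()], or a plain gene-by-sample matrix.
#' @param assignment Named integer vector gene -> module (as from
#'   [assign_modules()]); `NA` genes are skipped.
#' @param modules Optional subset of module ids to summarize.
#' @param tumor_only Use tumor samples only (default TRUE; ignored for plain
#'   matrices).
#' @return List with `values` (module-by-sample eigengene matrix) and
#'   `var_explained` (named vector).
#' @export
module_eigengenes <- function(omics, assignment, modules = NULL,
                              tumor_only = TRUE) {
  X <- if (inherits(omics, "OmicsMatrix")) {
    if (tumor_only) {
      omics$values[, omics$condition == "tumor", drop = FALSE]
    } else {
      omics$values
    }
  } else {
    omics
  }
  ids <- modules %||% sort(unique(assignment[!is.na(assignment)]))
  eg <- lapply(ids, function(k) {
    members <- intersect(names(assignment)[!is.na(assignment) &
                                           assignment == k],
                         rownames(X))
    if (length(members) == 0) return(NULL)
    compute_eigengene(standardize_rows(X[members, , drop = FALSE]))
  })
  keep <- !vapply(eg, is.null, logical(1))
  eg <- eg[keep]; ids <- ids[keep]
  values <- do.call(rbind, lapply(eg, `[[`, "values"))
  rownames(values) <- ids
  list(values = values,
       var_explained = stats::setNames(
         vapply(eg, `[[`, numeric(1), "var_explained"), ids))
}

#' Write an eigengene matrix and its variance-explained sidecar
#'
#' @param eg Result of [module_eigengenes()].
#' @param path Output TSV path for the module-by-sample matrix.
#' @param var_path Optional TSV path for variance explained.
#' @return `path`, invisibly.
#' @export
write_eigengenes <- function(eg, path, var_path = NULL) {
  tab <- data.frame(module = rownames(eg$values), eg$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, path)
  if (!is.null(var_path)) {
    write_tsv(data.frame(module = names(eg$var_explained),
                         var_explained = unname(eg$var_explained)),
              var_path)
  }
  invisible(path)
}
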