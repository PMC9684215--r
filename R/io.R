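#' Construct a gene-by-sample omics matrix with condition labels
#'
#' Container for one omics layer (log-normalized expression or methylation
#' beta/M-values). Genes are rows, samples are columns; every sample carries
#' a `tumor`/`normal` condition label. Rows containing missing values are
#' dropped (Pearson correlation and SVD downstream assume complete data).
#'
#' @param values Numeric gene-by-sample matrix with rownames (gene symbols)
#'   and colnames (sample ids).
#' @param condition Character vector of per-sample labels, values in
#'   `c("tumor", "normal")`, aligned with `colnames(values)`.
#' @return An object of class `OmicsMatrix`: a list with elements `values`,
#'   `gene_ids`, `sample_ids`, `condition`.
#' @export
omics_matrix <- function(values, condition) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("`values` must have gene rownames")
  if (is.null(colnames(values))) stop("`values` must have sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(values)) {
    stop("`condition` must have one label per sample")
  }
  if (!all(condition %in% c("tumor", "normal"))) {
    stop("condition labels must be 'tumor' or 'normal'")
  }
  miss <- rowSums(!is.finite(values)) > 0
  if (any(miss)) {
    message("dropping ", sum(miss), " gene(s) with missing values")
    values <- values[!miss, , drop = FALSE]
  }
  for (cond in unique(condition)) {
    if (sum(condition == cond) < 4) {
      stop("need at least 4 samples per condition; '", cond, "' has ",
           sum(condition == cond))
    }
  }
  structure(
    list(values = values, gene_ids = rownames(values),
         sample_ids = colnames(values), condition = condition),
    class = "OmicsMatrix"
  )
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat("OmicsMatrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples (",
      sum(x$condition == "tumor"), "tumor /",
      sum(x$condition == "normal"), "normal )\n")
  invisible(x)
}

#' Read a gene-by-sample matrix and its condition sidecar
#'
#' The matrix file is tab-separated with the gene id in the first column and
#' sample ids in the header row. The condition file is a two-column table
#' (sample id, condition) mapping every sample to `tumor` or `normal`.
#'
#' @param path Path to the TSV matrix.
#' @param condition_path Path to the sample-to-condition TSV.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, condition_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  cond <- utils::read.delim(condition_path, header = TRUE,
                            stringsAsFactors = FALSE)
  idx <- match(colnames(values), as.character(cond[[1]]))
  if (anyNA(idx)) {
    stop("samples missing from condition file: ",
         paste(colnames(values)[is.na(idx)], collapse = ", "))
  }
  omics_matrix(values, as.character(cond[[2]])[idx])
}

#' Construct an undirected gene-gene interaction network
#'
#' @param edges Two-column data frame or matrix of gene symbols. Self-loops
#'   are removed and duplicate unordered pairs collapsed.
#' @return Object of class `InteractionNetwork`: a list with a canonical
#'   two-column character `edges` data frame (a <= b lexicographically) and
#'   the implied `nodes`.
#' @export
interaction_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)[, 1:2]
  names(edges) <- c("a", "b")
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]
  edges$a[swap] <- edges$b[swap]
  edges$b[swap] <- tmp
  edges <- unique(edges)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = sort(unique(c(edges$a, edges$b)))),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat("InteractionNetwork:", nrow(x$edges), "edges,",
      length(x$nodes), "nodes\n")
  invisible(x)
}

#' Read a protein-interaction edge list
#'
#' Whitespace- or tab-separated file with two gene symbols per line; any
#' further columns are ignored.
#'
#' @param path Path to the edge-list file.
#' @return An [interaction_network()].
#' @export
read_interaction_network <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  interaction_network(tab[, 1:2])
}

#' Read a patient survival table
#'
#' Comma-separated file with columns `patient_id`, `time_days`, `event`
#' (1 = death observed, 0 = censored).
#'
#' @param path Path to the CSV.
#' @return A data frame of class `SurvivalTable`.
#' @export
read_survival_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  survival_table(tab[[1]], tab[[2]], tab[[3]])
}

#' Construct a survival table
#'
#' @param patient_id Character vector of patient/sample ids.
#' @param time_days Positive survival or follow-up times in days.
#' @param event Event indicator, 1 = death observed, 0 = censored.
#' @return Data frame with class `SurvivalTable`.
#' @export
survival_table <- function(patient_id, time_days, event) {
  time_days <- as.numeric(time_days)
  event <- as.integer(event)
  if (any(!is.finite(time_days)) || any(time_days <= 0)) {
    stop("survival times must be positive and finite")
  }
  if (!all(event %in% c(0L, 1L))) stop("event indicator must be 0 or 1")
  out <- data.frame(patient_id = as.character(patient_id),
                    time_days = time_days, event = event,
                    stringsAsFactors = FALSE)
  class(out) <- c("SurvivalTable", "data.frame")
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
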