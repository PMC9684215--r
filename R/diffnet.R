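#' Fisher z-transformation of a correlation coefficient
#'
#' \eqn{F(\rho) = \tfrac{1}{2}\ln\frac{1+\rho}{1-\rho}}. Correlations with
#' absolute value above `1 - 1e-12` are clipped to that bound (with a
#' warning) so that the transform stays finite on near-degenerate input.
#'
#' @param rho Numeric vector of correlations in (-1, 1).
#' @return Numeric vector of transformed values; an odd function of `rho`.
#' @export
fisher_transform <- function(rho) {
  if (any(!is.finite(rho))) stop("degenerate correlation: non-finite input")
  lim <- 1 - 1e-12
  if (any(abs(rho) > 1)) stop("degenerate correlation: |rho| > 1")
  if (any(abs(rho) > lim)) {
    warning("clipping ", sum(abs(rho) > lim), " correlation(s) at +/-", lim)
    rho <- pmin(pmax(rho, -lim), lim)
  }
  0.5 * log((1 + rho) / (1 - rho))
}

#' Differential co-expression z-statistic
#'
#' Difference of Fisher-transformed condition-specific correlations, scaled
#' by its asymptotic standard error:
#' \eqn{Z = (F(\rho_t) - F(\rho_n)) / \sqrt{1/(n_t-3) + 1/(n_n-3)}}.
#'
#' @param rho_t,rho_n Pearson correlations in tumor and normal samples.
#' @param n_t,n_n Sample counts per condition; both must exceed 3.
#' @return The z-statistic (vectorized over the correlations).
#' @export
differential_z <- function(rho_t, rho_n, n_t, n_n) {
  if (n_t <= 3) stop("tumor condition needs more than 3 samples (got ", n_t, ")")
  if (n_n <= 3) stop("normal condition needs more than 3 samples (got ", n_n, ")")
  (fisher_transform(rho_t) - fisher_transform(rho_n)) /
    sqrt(1 / (n_t - 3) + 1 / (n_n - 3))
}

#' Two-sided normal p-value for a differential z-statistic
#'
#' @param z Finite z-statistic(s).
#' @return \eqn{2(1 - \Phi(|z|))}, in \[0, 1\].
#' @export
edge_pvalue <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  2 * stats::pnorm(-abs(z))
}

#' Differentially expressed genes by Welch t-test
#'
#' Per-gene two-sample Welch t-test of tumor versus normal, Benjamini-
#' Hochberg corrected across genes. The test backing the "differentially
#' expressed genes" filter of the differential network is configurable in
#' principle; this is the package default.
#'
#' @param omics An [omics_matrix()].
#' @param fdr BH-adjusted significance threshold (default 0.05).
#' @return Character vector of significant gene ids (possibly empty).
#' @export
detect_de_genes <- function(omics, fdr = 0.05) {
  stopifnot(inherits(omics, "OmicsMatrix"))
  xt <- omics$values[, omics$condition == "tumor", drop = FALSE]
  xn <- omics$values[, omics$condition == "normal", drop = FALSE]
  mt <- rowMeans(xt); mn <- rowMeans(xn)
  vt <- apply(xt, 1, stats::var); vn <- apply(xn, 1, stats::var)
  nt <- ncol(xt); nn <- ncol(xn)
  se2 <- vt / nt + vn / nn
  tstat <- (mt - mn) / sqrt(se2)
  df <- se2^2 / ((vt / nt)^2 / (nt - 1) + (vn / nn)^2 / (nn - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1  # zero-variance genes in both conditions
  padj <- stats::p.adjust(p, method = "BH")
  omics$gene_ids[padj < fdr]
}

#' Build a weighted differential co-expression network
#'
#' For every interaction-network edge among measured genes, Pearson
#' correlations are computed per condition, converted to the differential
#' z-statistic, and BH-corrected across all tested edges. `|Z|` is the edge
#' weight. Edges with adjusted p below `fdr` are flagged as significant
#' differential co-expression (DCE). Genes that do not show significant DCE
#' with a differentially expressed gene are then removed, and edges incident
#' to removed genes pruned; non-significant surviving edges keep their `|Z|`
#' weight.
#'
#' @param omics An [omics_matrix()] (expression or methylation layer).
#' @param ppi An [interaction_network()].
#' @param fdr BH threshold for significant DCE edges (default 0.05).
#' @param de_genes Optional precomputed DE gene set; defaults to
#'   [detect_de_genes()] on `omics`.
#' @return Object of class `DifferentialNetwork`: list with `edges` (data
#'   frame over retained genes: geneA, geneB, rho_t, rho_n, Z, weight, p,
#'   p_adj, significant), `tested_edges` (the same table before the gene
#'   filter), `retained_genes`, and the condition sample counts.
#' @export
build_differential_network <- function(omics, ppi, fdr = 0.05,
                                       de_genes = NULL) {
  stopifnot(inherits(omics, "OmicsMatrix"), inherits(ppi, "InteractionNetwork"))
  genes <- sort(omics$gene_ids)
  ed <- ppi$edges
  ed <- ed[ed$a %in% genes & ed$b %in% genes, , drop = FALSE]
  if (nrow(ed) == 0) stop("no interaction edges among measured genes")

  xt <- t(omics$values[, omics$condition == "tumor", drop = FALSE])
  xn <- t(omics$values[, omics$condition == "normal", drop = FALSE])
  n_t <- nrow(xt); n_n <- nrow(xn)
  sd0 <- colnames(xt)[apply(xt, 2, stats::sd) == 0 |
                      apply(xn, 2, stats::sd) == 0]
  if (length(sd0) > 0) {
    drop <- ed$a %in% sd0 | ed$b %in% sd0
    if (any(drop)) {
      warning("dropping ", sum(drop),
              " edge(s) touching zero-variance gene(s): ",
              paste(utils::head(sd0, 5), collapse = ", "))
      ed <- ed[!drop, , drop = FALSE]
    }
    if (nrow(ed) == 0) stop("no testable edges left after variance filter")
  }

  used <- sort(unique(c(ed$a, ed$b)))
  ct <- stats::cor(xt[, used, drop = FALSE])
  cn <- stats::cor(xn[, used, drop = FALSE])
  ia <- match(ed$a, used); ib <- match(ed$b, used)
  rho_t <- ct[cbind(ia, ib)]
  rho_n <- cn[cbind(ia, ib)]
  z <- differential_z(rho_t, rho_n, n_t, n_n)
  p <- edge_pvalue(z)
  p_adj <- stats::p.adjust(p, method = "BH")
  edges <- data.frame(geneA = ed$a, geneB = ed$b,
                      rho_t = rho_t, rho_n = rho_n,
                      Z = z, weight = abs(z), p = p, p_adj = p_adj,
                      significant = p_adj < fdr,
                      stringsAsFactors = FALSE)

  if (is.null(de_genes)) de_genes <- detect_de_genes(omics)
  sig <- edges[edges$significant, , drop = FALSE]
  keep <- unique(c(sig$geneA[sig$geneB %in% de_genes],
                   sig$geneB[sig$geneA %in% de_genes]))
  retained <- sort(keep)
  tested_edges <- edges
  edges <- edges[edges$geneA %in% retained & edges$geneB %in% retained, ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, tested_edges = tested_edges,
                 retained_genes = retained,
                 de_genes = de_genes, n_t = n_t, n_n = n_n, fdr = fdr),
            class = "DifferentialNetwork")
}

#' @export
print.DifferentialNetwork <- function(x, ...) {
  cat("DifferentialNetwork:", nrow(x$edges), "edges on",
      length(x$retained_genes), "retained genes (",
      sum(x$edges$significant), "significant DCE )\n")
  invisible(x)
}

#' Dense similarity matrix of a differential network
#'
#' `a_ij = |Z|` for edges of the differential network, 0 elsewhere;
#' symmetric with zero diagonal, over the retained genes.
#'
#' @param dn A `DifferentialNetwork`.
#' @param genes Optional gene set to build over (defaults to
#'   `dn$retained_genes`).
#' @return Symmetric nonnegative numeric matrix with gene dimnames.
#' @export
to_similarity_matrix <- function(dn, genes = NULL) {
  stopifnot(inherits(dn, "DifferentialNetwork"))
  genes <- genes %||% dn$retained_genes
  if (length(genes) == 0) stop("retained gene set is empty")
  A <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  ed <- dn$edges[dn$edges$geneA %in% genes & dn$edges$geneB %in% genes, ]
  if (nrow(ed) > 0) {
    ia <- match(ed$geneA, genes); ib <- match(ed$geneB, genes)
    A[cbind(ia, ib)] <- ed$weight
    A[cbind(ib, ia)] <- ed$weight
  }
  A
}

#' Write a differential-network edge table
#'
#' @param dn A `DifferentialNetwork`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_differential_network <- function(dn, path) {
  write_tsv(dn$edges, path)
}
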