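#' Module density
#'
#' Mean similarity over ordered distinct gene pairs inside a module:
#' \eqn{\mathrm{density}(M) = \sum_{p \ne q \in M} a_{pq} / (|M|(|M|-1))}.
#' Self-pairs are excluded (the similarity matrix has zero diagonal).
#' A singleton module has an undefined denominator; its density is reported
#' as 0 with a warning.
#'
#' @param members Character vector of gene ids (or integer indices into `A`).
#' @param A Symmetric similarity matrix with gene dimnames.
#' @return Nonnegative scalar density.
#' @export
module_density <- function(members, A) {
  m <- length(members)
  if (m < 2) {
    warning("singleton module: density defined as 0")
    return(0)
  }
  sub <- A[members, members, drop = FALSE]
  (sum(sub) - sum(diag(sub))) / (m * (m - 1))
}

#' Permutation test for module density
#'
#' Draws `B` gene sets of the same size uniformly without replacement from
#' the background (the rows of `A`) and reports the fraction whose density
#' is greater than or equal to the observed density. p = 0 is possible by
#' construction.
#'
#' @param members Module gene ids.
#' @param A Similarity matrix over the background gene set.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @return Permutation p-value in \[0, 1\].
#' @export
density_permutation_test <- function(members, A, B = 1000, seed = NULL) {
  bg <- rownames(A) %||% seq_len(nrow(A))
  m <- length(members)
  if (m >= length(bg)) stop("module size must be below the background size")
  obs <- suppressWarnings(module_density(members, A))
  null <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      suppressWarnings(module_density(sample(bg, m), A))
    }, numeric(1))
  })
  mean(null >= obs)
}

build_module_set <- function(assignment, A, B, alpha, seed) {
  ids <- sort(unique(assignment[!is.na(assignment)]))
  rows <- lapply(seq_along(ids), function(i) {
    k <- ids[i]
    members <- names(assignment)[!is.na(assignment) & assignment == k]
    dens <- suppressWarnings(module_density(members, A))
    p <- if (length(members) < nrow(A)) {
      density_permutation_test(members, A, B = B, seed = derive_seed(seed, i))
    } else {
      NA_real_
    }
    data.frame(module = k, size = length(members), density = dens, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  # Bonferroni within this rank: family = modules produced at this rank
  tab$p_adj <- pmin(1, tab$p * nrow(tab))
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < alpha
  structure(list(assignment = assignment, modules = tab, alpha = alpha),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat("ModuleSet:", nrow(x$modules), "modules (",
      sum(x$modules$significant), "significant at alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Rank selection for symmetric NMF by counted significant modules
#'
#' For every candidate rank `k`, runs [symnmf()], assigns genes to modules,
#' permutation-tests each module's density against same-size random gene
#' sets, and Bonferroni-corrects the density p-values within the rank
#' (correction factor = number of modules produced at that rank). The rank
#' producing the largest number of significant modules wins; ties go to the
#' smallest rank.
#'
#' @param A Similarity matrix (symmetric, nonnegative, gene dimnames).
#' @param k_grid Integer vector of candidate ranks, each `< nrow(A)`.
#' @param B Permutations per module density test (default 1000).
#' @param alpha Significance level on the Bonferroni-adjusted density p
#'   (default 0.05).
#' @param seed Integer seed.
#' @param restarts Seeded [symnmf()] restarts per rank (default 3).
#' @param ... Further arguments passed to [symnmf()].
#' @return List with `K` (selected rank), `module_set` (the [ModuleSet] at
#'   `K`), `factor` (its `SymFactor`), and `profile` (data frame of rank vs
#'   number of significant modules).
#' @export
select_rank <- function(A, k_grid, B = 1000, alpha = 0.05, seed = NULL,
                        restarts = 3, ...) {
  if (length(k_grid) == 0) stop("k_grid must be nonempty")
  if (any(k_grid >= nrow(A))) stop("every candidate rank must be < nrow(A)")
  fits <- lapply(seq_along(k_grid), function(i) {
    k <- k_grid[i]
    f <- symnmf(A, k, seed = derive_seed(seed %||% 0, 1000 + i),
                restarts = restarts, ...)
    ms <- build_module_set(assign_modules(f), A, B = B, alpha = alpha,
                           seed = derive_seed(seed %||% 0, 2000 + i * 100))
    list(factor = f, module_set = ms,
         n_significant = sum(ms$modules$significant))
  })
  nsig <- vapply(fits, `[[`, numeric(1), "n_significant")
  ord <- order(-nsig, k_grid)
  best <- ord[1]
  list(K = k_grid[best],
       module_set = fits[[best]]$module_set,
       factor = fits[[best]]$factor,
       profile = data.frame(k = k_grid, n_significant = nsig))
}

inter_adjacency <- function(Mi, Mj, A) {
  sum(A[Mi, Mj, drop = FALSE]) / (length(Mi) * length(Mj))
}

#' Separability score between two modules
#'
#' \eqn{1 - \mathrm{interAdj}(M_i, M_j) / \sqrt{\mathrm{density}(M_i)\,
#' \mathrm{density}(M_j)}}, where interAdj is the mean cross-module
#' similarity. Scores close to 1 mean well-separated modules. If either
#' module has zero density the score is undefined (`NA`, with a warning).
#'
#' @param Mi,Mj Disjoint gene sets.
#' @param A Similarity matrix.
#' @return Scalar score (at most 1), or `NA`.
#' @export
separability <- function(Mi, Mj, A) {
  if (length(intersect(Mi, Mj)) > 0) stop("modules must be disjoint")
  di <- suppressWarnings(module_density(Mi, A))
  dj <- suppressWarnings(module_density(Mj, A))
  if (di <= 0 || dj <= 0) {
    warning("separability undefined: a module has zero density")
    return(NA_real_)
  }
  1 - inter_adjacency(Mi, Mj, A) / sqrt(di * dj)
}

#' Permutation test for module separability
#'
#' Null distribution: random disjoint gene-set pairs of the same sizes drawn
#' uniformly from the background. By default p is the fraction of null pairs
#' with separability greater than or equal to the observed score; the tail
#' is configurable (`tail = "less"` tests for unusually low separability).
#' Null draws whose score is undefined (zero-density module) are dropped.
#'
#' @param Mi,Mj Disjoint gene sets with positive density.
#' @param A Similarity matrix.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param tail `"greater"` (default) or `"less"`.
#' @return Permutation p-value.
#' @export
separability_permutation_test <- function(Mi, Mj, A, B = 1000, seed = NULL,
                                          tail = c("greater", "less")) {
  tail <- match.arg(tail)
  bg <- rownames(A) %||% seq_len(nrow(A))
  ni <- length(Mi); nj <- length(Mj)
  if (ni + nj > length(bg)) stop("modules larger than the background")
  obs <- separability(Mi, Mj, A)
  if (is.na(obs)) stop("observed separability undefined")
  null <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      pick <- sample(bg, ni + nj)
      suppressWarnings(separability(pick[seq_len(ni)], pick[-seq_len(ni)], A))
    }, numeric(1))
  })
  null <- null[!is.na(null)]
  if (length(null) == 0) return(NA_real_)
  if (tail == "greater") mean(null >= obs) else mean(null <= obs)
}

#' Pairwise separability report for a module set
#'
#' @param module_set A [ModuleSet].
#' @param A Similarity matrix.
#' @param B Permutations per pair (default 1000).
#' @param seed Integer seed.
#' @param significant_only Restrict to significant modules (default TRUE).
#' @return List with square matrices `score` and `p` (NA diagonal).
#' @export
separability_report <- function(module_set, A, B = 1000, seed = NULL,
                                significant_only = TRUE) {
  stopifnot(inherits(module_set, "ModuleSet"))
  tab <- module_set$modules
  if (significant_only) tab <- tab[tab$significant, , drop = FALSE]
  ids <- tab$module
  k <- length(ids)
  score <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  pval <- score
  asg <- module_set$assignment
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      Mi <- names(asg)[!is.na(asg) & asg == ids[i]]
      Mj <- names(asg)[!is.na(asg) & asg == ids[j]]
      s <- suppressWarnings(separability(Mi, Mj, A))
      score[i, j] <- score[j, i] <- s
      if (!is.na(s)) {
        p <- separability_permutation_test(
          Mi, Mj, A, B = B, seed = derive_seed(seed %||% 0, i * 1000 + j))
        pval[i, j] <- pval[j, i] <- p
      }
    }
  }
  list(score = score, p = pval)
}

#' Write a per-gene module table
#'
#' @param module_set A [ModuleSet].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_module_table <- function(module_set, path) {
  asg <- module_set$assignment
  tab <- data.frame(gene = names(asg), module_id = unname(asg),
                    stringsAsFactors = FALSE)
  tab <- merge(tab, module_set$modules, by.x = "module_id", by.y = "module",
               all.x = TRUE, sort = FALSE)
  tab <- tab[order(tab$module_id, tab$gene),
             c("gene", "module_id", "size", "density", "p", "p_adj",
               "significant")]
  names(tab)[3] <- "module_size"
  write_tsv(tab, path)
}
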