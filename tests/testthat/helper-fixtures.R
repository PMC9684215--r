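# Shared fixture builders and independent oracles.

# Block-structured similarity matrix: `sizes` blocks with `within` weight
# inside blocks and `cross` weight between them; zero diagonal.
block_similarity <- function(sizes, within = 1, cross = 0) {
  n <- sum(sizes)
  A <- matrix(cross, n, n)
  off <- 0
  for (s in sizes) {
    idx <- off + seq_len(s)
    A[idx, idx] <- within
    off <- off + s
  }
  diag(A) <- 0
  rownames(A) <- colnames(A) <- paste0("g", seq_len(n))
  A
}

# Independent conjugate normal-inverse-gamma update, written directly from
# the generic precision-form completion of the square with prior
# N(beta0, g * sigma^2 * (X'X)^-1) and the improper IG(0, 0) variance prior.
# Deliberately a different derivation from the package's shrinkage-identity
# implementation.
conjugate_oracle <- function(X, y, g, beta0) {
  n <- nrow(X)
  XtX <- crossprod(X)
  V0inv <- XtX / g
  Vn <- solve(V0inv + XtX)
  mn <- Vn %*% (V0inv %*% beta0 + crossprod(X, y))
  bn <- (sum(y^2) + drop(t(beta0) %*% V0inv %*% beta0) -
           drop(t(mn) %*% (V0inv + XtX) %*% mn)) / 2
  list(mean = as.numeric(mn), a = n / 2, b = bn)
}

# Exhaustive module-density permutation p: enumerate every same-size subset
# of the background and count those at least as dense as the observed set.
exact_density_p <- function(members, A) {
  bg <- rownames(A)
  obs <- suppressWarnings(episubnet::module_density(members, A))
  sets <- utils::combn(bg, length(members), simplify = FALSE)
  dens <- vapply(sets, function(s) {
    suppressWarnings(episubnet::module_density(s, A))
  }, numeric(1))
  mean(dens >= obs)
}

# Hand-coded Cox partial likelihood for a single covariate with untied event
# times, maximized numerically; independent of the survival package.
cox_oracle_1cov <- function(x, time, event) {
  loglik <- function(beta) {
    ord <- order(time)
    x <- x[ord]; event <- event[ord]
    eta <- beta * x
    # risk set of subject i: all with time >= time_i (times are distinct)
    ll <- 0
    for (i in seq_along(x)) {
      if (event[i] == 1) {
        ll <- ll + eta[i] - log(sum(exp(eta[i:length(x)])))
      }
    }
    ll
  }
  stats::optimize(loglik, c(-10, 10), maximum = TRUE)$maximum
}

# Two-condition omics fixture with planted differential co-expression: two
# modules whose genes share a common factor in tumor only, plus a tumor
# mean shift (so the module genes are differentially expressed), plus
# background genes.
make_dce_omics <- function(prefix, module_sizes = c(8, 8), n_bg = 6,
                           n_t = 60, n_n = 60, shift = 2, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    rows <- list()
    for (m in seq_along(module_sizes)) {
      f_t <- rnorm(n_t)
      for (g in seq_len(module_sizes[m])) {
        tum <- 0.9 * f_t + 0.45 * rnorm(n_t) + shift
        nor <- rnorm(n_n)
        rows[[paste0(prefix, m, "_", g)]] <- c(tum, nor)
      }
    }
    for (g in seq_len(n_bg)) {
      rows[[paste0(prefix, "bg_", g)]] <- rnorm(n_t + n_n)
    }
    values <- do.call(rbind, rows)
    colnames(values) <- paste0("s", seq_len(n_t + n_n))
    episubnet::omics_matrix(values,
                            rep(c("tumor", "normal"), c(n_t, n_n)))
  })
}

# All within-module pairs of a set of modules as an edge data frame.
module_clique_edges <- function(gene_lists) {
  do.call(rbind, lapply(gene_lists, function(gs) {
    t(utils::combn(gs, 2))
  }))
}
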