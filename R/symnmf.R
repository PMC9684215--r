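#' Symmetric nonnegative matrix factorization
#'
#' Factorizes a symmetric nonnegative similarity matrix as
#' \eqn{A \approx H H^T} with \eqn{H \ge 0} by minimizing the squared
#' Frobenius loss \eqn{\|A - HH^T\|_F^2}. The solver is projected gradient
#' descent with a backtracking line search, so the objective is
#' nonincreasing at every iteration. `H` is initialized from
#' `runif(0, 2*sqrt(mean(A)/K))` under the given seed; with `restarts > 1`
#' the best of several seeded runs (lowest final loss) is returned.
#'
#' @param A Symmetric nonnegative matrix (zero diagonal allowed); asymmetry
#'   beyond 1e-8 is an error.
#' @param K Factorization rank, `1 <= K < nrow(A)`.
#' @param max_iter Maximum iterations per run (default 500).
#' @param tol Relative loss-change convergence tolerance (default 1e-5).
#' @param seed Integer seed; runs are deterministic given the seed.
#' @param restarts Number of seeded restarts (default 1).
#' @return Object of class `SymFactor`: list with `H` (n x K, carries
#'   rownames of `A`), `K`, `loss` (final squared Frobenius objective),
#'   `loss_trace`, `n_iter`, `seed`.
#' @export
symnmf <- function(A, K, max_iter = 500, tol = 1e-5, seed = NULL,
                   restarts = 1) {
  stopifnot(is.matrix(A), is.numeric(A))
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric (tolerance 1e-8)")
  if (any(A < 0)) stop("A must be nonnegative")
  if (K >= n) stop("rank K must be smaller than nrow(A)")
  if (K < 1) stop("rank K must be at least 1")

  runs <- lapply(seq_len(restarts), function(r) {
    symnmf_run(A, K, max_iter, tol,
               if (is.null(seed)) NULL else derive_seed(seed, r - 1))
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "loss"))]]
  rownames(best$H) <- rownames(A)
  best$seed <- seed
  structure(best, class = "SymFactor")
}

symnmf_run <- function(A, K, max_iter, tol, seed) {
  n <- nrow(A)
  H <- with_seed(seed, {
    hi <- 2 * sqrt(mean(A) / K)
    matrix(stats::runif(n * K, 0, max(hi, .Machine$double.eps)), n, K)
  })
  loss_fn <- function(H) {
    R <- tcrossprod(H) - A
    sum(R * R)
  }
  loss <- loss_fn(H)
  trace <- loss
  step <- 1 / max(4 * sum(diag(crossprod(H))), 1)
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    grad <- 4 * (tcrossprod(H) %*% H - A %*% H)
    accepted <- FALSE
    for (bt in seq_len(40)) {
      Hn <- pmax(H - step * grad, 0)
      ln <- loss_fn(Hn)
      if (ln <= loss) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    rel <- if (loss > 0) (loss - ln) / loss else 0
    H <- Hn
    loss <- ln
    trace <- c(trace, loss)
    step <- step * 2
    if (rel < tol) break
  }
  list(H = H, K = K, loss = loss, loss_trace = trace, n_iter = it)
}

#' @export
print.SymFactor <- function(x, ...) {
  cat("SymFactor: rank", x$K, "on", nrow(x$H), "genes; loss",
      format(x$loss, digits = 6), "after", x$n_iter, "iterations\n")
  invisible(x)
}

#' Hard module assignment from a symmetric factorization
#'
#' Gene `i` is assigned to the module whose column of `H` carries the
#' largest entry in row `i`; ties are broken toward the lowest module index.
#' All-zero rows cannot be assigned and come back as `NA` (with a warning).
#'
#' @param f A `SymFactor` from [symnmf()].
#' @return Integer vector of module indices in `1..K`, named by gene,
#'   `NA` for unassigned genes.
#' @export
assign_modules <- function(f) {
  stopifnot(inherits(f, "SymFactor"))
  H <- f$H
  if (nrow(H) == 0) stop("empty factor matrix")
  idx <- max.col(H, ties.method = "first")
  zero <- rowSums(H) == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero factor rows left unassigned")
    idx[zero] <- NA_integer_
  }
  names(idx) <- rownames(H)
  idx
}
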