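#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a global seed
#'
#' Counter-based fan-out of one user-supplied seed into independent child
#' seeds for the pipeline's stages, permutation tests and factorization
#' restarts, kept below 2^31 - 1 so they are valid R integer seeds. Every
#' seeded routine in the package derives its own stream this way, which
#' makes whole-pipeline runs reproducible from a single integer.
#'
#' @param seed Integer global seed.
#' @param index Nonnegative integer counter.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(2L)) s <- (s * 48271) %% 2147483647
  as.integer((s + as.double(index) * 2654435761) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
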