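#' Cox proportional-hazards coefficients for module eigengenes
#'
#' Multivariate Cox partial-likelihood fit of survival on one or more
#' eigengene covariates (Efron tie handling), via the `survival` package.
#' Requires at least 10 observed events.
#'
#' @param covariates Numeric vector, or patient-by-covariate matrix/data
#'   frame, aligned with `surv` rows.
#' @param surv A [survival_table()].
#' @return Named numeric vector of Cox coefficients.
#' @export
fit_cox <- function(covariates, surv) {
  stopifnot(inherits(surv, "SurvivalTable"))
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("cov", seq_len(ncol(X)))
  if (nrow(X) != nrow(surv)) stop("covariates and survival table differ in length")
  if (any(!is.finite(X))) stop("covariates must be finite")
  if (sum(surv$event) < 10) {
    stop("need at least 10 observed events (got ", sum(surv$event), ")")
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(surv$time_days, surv$event) ~ X,
                    ties = "efron"),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w)),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e))
  )
  stats::setNames(as.numeric(stats::coef(fit)), colnames(X))
}

#' Prognostic index from Cox coefficients and eigengenes
#'
#' Per-patient linear score \eqn{PI_i = \sum_c \beta^{cox}_c E_{ci}}; a
#' single-module PI is just \eqn{\beta\,E}.
#'
#' @param beta_cox Cox coefficient vector.
#' @param eigengenes Per-patient eigengene values: vector (one module) or
#'   patient-by-module matrix matching `beta_cox`.
#' @return Numeric PI per patient.
#' @export
prognostic_index <- function(beta_cox, eigengenes) {
  E <- as.matrix(eigengenes)
  if (ncol(E) != length(beta_cox)) stop("dimension mismatch")
  as.numeric(E %*% beta_cox)
}

#' Stratify patients into risk groups by prognostic index
#'
#' Low risk: PI strictly below the 30th percentile; high risk: PI strictly
#' above the 70th percentile; patients in between are labelled `mid` and
#' excluded from the two-group survival test. Percentiles use linear
#' interpolation by default (`type = 7`); `type = 1` gives the nearest-rank
#' alternative.
#'
#' @param pis Numeric PI vector, at least 10 patients, not all equal.
#' @param type Quantile type passed to [stats::quantile()] (default 7).
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
risk_groups <- function(pis, type = 7) {
  if (length(pis) < 10) stop("need at least 10 patients")
  if (max(pis) == min(pis)) stop("degenerate PI: all values equal")
  q <- stats::quantile(pis, c(0.3, 0.7), type = type, names = FALSE)
  factor(ifelse(pis < q[1], "low", ifelse(pis > q[2], "high", "mid")),
         levels = c("low", "mid", "high"))
}

#' Kaplan-Meier curves and log-rank test for two risk groups
#'
#' Product-limit survival curves per group and the two-group log-rank
#' chi-squared p-value (`mid` patients are excluded). A group with zero
#' events is flagged.
#'
#' @param groups Factor from [risk_groups()] (or any factor whose `low` and
#'   `high` levels are compared).
#' @param surv A [survival_table()] aligned with `groups`.
#' @return List with `km` (a `survfit` object), `p` (log-rank p-value),
#'   `flagged` (TRUE if a compared group has no events), and `groups_used`.
#' @export
km_logrank <- function(groups, surv) {
  stopifnot(inherits(surv, "SurvivalTable"))
  keep <- groups %in% c("low", "high")
  g <- droplevels(factor(groups[keep], levels = c("low", "high")))
  s <- surv[keep, , drop = FALSE]
  if (nlevels(g) < 2) stop("both risk groups must be nonempty")
  if (sum(s$event) < 1) stop("need at least one event")
  flagged <- any(tapply(s$event, g, sum) == 0)
  if (flagged) warning("a risk group has zero events; p-value flagged")
  so <- survival::Surv(s$time_days, s$event)
  km <- survival::survfit(so ~ g)
  sd <- survival::survdiff(so ~ g)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(km = km, p = p, flagged = flagged, groups_used = g)
}

#' Screen eigengenes against observed survival time
#'
#' Pearson correlation between a module eigengene and survival time among
#' patients whose death was observed (event = 1), with a permutation z-test:
#' the correlation is recomputed under `B` random reorderings of the
#' survival times and the observed value is compared with the null mean and
#' standard deviation.
#'
#' @param eigengene Per-patient eigengene values.
#' @param surv A [survival_table()] aligned with `eigengene`.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `cor`, `z`, and two-sided `p`.
#' @export
eigengene_survival_screen <- function(eigengene, surv, B = 1000,
                                      seed = NULL) {
  stopifnot(inherits(surv, "SurvivalTable"))
  dead <- surv$event == 1
  if (sum(dead) < 4) stop("need at least 4 patients with observed death")
  e <- eigengene[dead]
  t0 <- surv$time_days[dead]
  obs <- stats::cor(e, t0)
  null <- with_seed(seed, {
    vapply(seq_len(B), function(b) stats::cor(e, sample(t0)), numeric(1))
  })
  z <- (obs - mean(null)) / stats::sd(null)
  list(cor = obs, z = z, p = 2 * stats::pnorm(-abs(z)))
}
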