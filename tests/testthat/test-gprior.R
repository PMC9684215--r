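make_toy <- function(n = 20, k = 2, seed = 1, beta = NULL, sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
  beta <- beta %||% rnorm(k)
  y <- as.numeric(X %*% beta + sd * rnorm(n))
  list(X = X, y = y, beta = beta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("biological relatedness counts cross edges", {
  ppi <- interaction_network(expand.grid(a = paste0("p", 1:5),
                                         b = paste0("r", 1:5),
                                         stringsAsFactors = FALSE))
  expect_equal(biological_relatedness(paste0("p", 1:5), paste0("r", 1:5),
                                      ppi), 5)
  ppi0 <- interaction_network(data.frame(a = "p1", b = "p2"))
  expect_equal(biological_relatedness(paste0("p", 1:3), paste0("r", 1:3),
                                      ppi0), 0)
  # adding a cross edge never decreases r
  ppi1 <- interaction_network(rbind(ppi0$edges,
                                    data.frame(a = "p1", b = "r1")))
  expect_gt(biological_relatedness(paste0("p", 1:3), paste0("r", 1:3), ppi1),
            0)
  expect_error(biological_relatedness(character(0), "r1", ppi0), "empty")
})

test_that("posterior mean shrinks OLS per coordinate as g dictates", {
  # single predictor crafted so beta_ols is exactly 0.6
  set.seed(2)
  x <- c(scale(rnorm(30, 0, 1)))  # mean 0
  r <- stats::resid(stats::lm(rnorm(30) ~ x - 1))
  X <- matrix(x, dimnames = list(NULL, "x1"))
  y <- 0.6 * x + r
  expect_equal(posterior_beta(X, y, g = 1)$beta_tilde, 0.3)
  expect_equal(posterior_beta(X, y, g = 0)$beta_tilde, 0)
  expect_equal(posterior_beta(X, y, g = 1e9)$beta_tilde, 0.6,
               tolerance = 1e-6)
  # vector g: one coordinate fully shrunk, the other untouched
  toy <- make_toy(n = 40, k = 2, seed = 3)
  pb <- posterior_beta(toy$X, toy$y, g = c(0, 1e12))
  expect_equal(pb$beta_tilde[1], 0)
  expect_equal(pb$beta_tilde[2], pb$beta_ols[2], tolerance = 1e-9)
})

test_that("posterior matches an independent conjugate-update oracle", {
  for (i in 1:50) {
    k <- 1 + (i %% 3)
    toy <- make_toy(n = 20, k = k, seed = 100 + i)
    g <- stats::runif(1, 0.1, 10)
    beta0 <- stats::rnorm(k)
    pb <- posterior_beta(toy$X, toy$y, g = g, beta0 = beta0)
    ps <- posterior_sigma2(toy$X, toy$y, g = g, beta0 = beta0)
    or <- conjugate_oracle(toy$X, toy$y, g, beta0)
    expect_equal(pb$beta_tilde, or$mean, tolerance = 1e-10)
    expect_equal(ps$a, or$a, tolerance = 1e-10)
    expect_equal(ps$b, or$b, tolerance = 1e-10)
  }
})

test_that("shrinkage is monotone in g", {
  toy <- make_toy(n = 30, k = 1, seed = 5)
  gs <- c(0, 0.1, 0.5, 1, 2, 10, 100)
  betas <- vapply(gs, function(g) {
    abs(posterior_beta(toy$X, toy$y, g = g)$beta_tilde)
  }, numeric(1))
  expect_true(all(diff(betas) >= -1e-12))
})

test_that("error-variance posterior has the documented scale", {
  # perfect fit: b reduces to the shrinkage quadratic
  set.seed(61)
  x <- rnorm(15)
  X <- matrix(x, dimnames = list(NULL, "x1"))
  y <- 2 * x
  ps <- posterior_sigma2(X, y, g = 3)
  expect_equal(ps$b, 4 * sum(x^2) / (2 * 4), tolerance = 1e-10)
  expect_equal(ps$a, 7.5)
  # g -> infinity: prior quadratic vanishes
  toy <- make_toy(n = 25, k = 2, seed = 6)
  f <- stats::lm.fit(toy$X, toy$y)
  ps2 <- posterior_sigma2(toy$X, toy$y, g = 1e12)
  expect_equal(ps2$b, sum(f$residuals^2) / 2, tolerance = 1e-6)
  # collinear designs are refused with the predictor named
  Xc <- cbind(x1 = x, x2 = 2 * x)
  expect_error(posterior_sigma2(Xc, y, g = 1), "collinear")
})

test_that("expected BIC penalizes exactly k log(n) for equal fits", {
  # x2 orthogonal to both x1 and y: adding it leaves (a, b) unchanged
  set.seed(7)
  n <- 24
  x1 <- c(scale(rnorm(n)))
  y0 <- c(scale(rnorm(n)))
  qrt <- qr(cbind(x1, y0))
  x2 <- c(scale(qr.resid(qrt, rnorm(n))))
  y <- 0.5 * x1 + y0
  X1 <- matrix(x1, dimnames = list(NULL, "x1"))
  X12 <- cbind(x1 = x1, x2 = x2)
  g <- 2
  d <- expected_bic(X12, y, g = c(g, g)) - expected_bic(X1, y, g = g)
  expect_equal(d, log(n), tolerance = 1e-8)
})

test_that("expected log-variance uses ln(b) - digamma(a)", {
  # craft a = n/2 = 5 and b ~ SSR/2 = 10 with a huge g
  set.seed(8)
  n <- 10
  x <- c(scale(rnorm(n)))
  r <- stats::resid(stats::lm(rnorm(n) ~ x - 1))
  r <- r * sqrt(20 / sum(r^2))
  y <- 0.7 * x + r
  X <- matrix(x, dimnames = list(NULL, "x1"))
  eb <- expected_bic(X, y, g = 1e12)
  expect_equal(eb, n * (log(10) - digamma(5)) + log(n), tolerance = 1e-5)
  expect_equal(log(10) - digamma(5), 0.7964675, tolerance = 1e-7)
})

test_that("subset search returns the expected-BIC minimizer", {
  toy <- make_toy(n = 50, k = 1, seed = 9)
  fit <- best_subset(toy$X, toy$y, g = 2)
  expect_equal(fit$predictors, "x1")  # single candidate
  # planted signal among noise predictors
  set.seed(10)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- 0.3 * X[, 1] + 0.3 * rnorm(n)
  fit2 <- best_subset(X, y, g = rep(1, 4))
  expect_equal(fit2$predictors, "x1")
  expect_lt(fit2$coef_p[["x1"]], 1e-6)
})

test_that("a pure-noise predictor raises the expected BIC", {
  worse <- 0
  for (s in 1:100) {
    set.seed(300 + s)
    n <- 200
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 0.5 * x1 + rnorm(n)
    X1 <- cbind(x1 = x1)
    X12 <- cbind(x1 = x1, x2 = x2)
    if (expected_bic(X12, y, g = c(2, 2)) >
        expected_bic(X1, y, g = 2)) worse <- worse + 1
  }
  expect_gte(worse, 90)
})

test_that("coefficient significance is calibrated as documented", {
  # fully shrunk coefficient: p = 1
  toy <- make_toy(n = 30, k = 1, seed = 11)
  fit <- best_subset(toy$X, toy$y, g = 0)
  expect_equal(unname(fit$coef_p), 1)
  # strong planted association
  set.seed(12)
  n <- 200
  X <- matrix(rnorm(n), dimnames = list(NULL, "x1"))
  y <- 0.3 * X[, 1] + 0.3 * rnorm(n)
  expect_lt(best_subset(X, y, g = 2)$coef_p[["x1"]], 1e-6)
  # null calibration: baseline t-test p-values are uniform...
  p_ols <- vapply(1:200, function(s) {
    toy <- make_toy(n = 25, k = 1, seed = 4000 + s, beta = 0)
    no_prior_baseline(toy$X, toy$y)$coef_p[[1]]
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(p_ols, "punif"))$p.value, 0.01)
  # ...and the g-prior z-test is conservative at moderate g (shrunk z)
  p_g <- vapply(1:200, function(s) {
    toy <- make_toy(n = 25, k = 1, seed = 4000 + s, beta = 0)
    best_subset(toy$X, toy$y, g = 1)$coef_p[[1]]
  }, numeric(1))
  expect_lt(mean(p_g < 0.05), 0.05)
  expect_gt(mean(p_g), 0.5)
})

test_that("within-subnetwork correlation permutation test is exact-tailed", {
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- as.numeric(X %*% c(1, -1))  # exact linear combination
  ct <- subnetwork_correlation_test(X, y, B = 99, seed = 1)
  expect_equal(ct$p, 1 / 100)
  expect_equal(ct$statistic, 1, tolerance = 1e-10)
  expect_error(subnetwork_correlation_test(X, y, B = 0), "at least 1")
  # independent response: p roughly uniform over replicates
  ps <- vapply(1:60, function(s) {
    set.seed(600 + s)
    subnetwork_correlation_test(X, rnorm(n), B = 99, seed = s)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  # pairwise statistic variant runs
  ct2 <- subnetwork_correlation_test(X, y, B = 49, seed = 2,
                                     statistic = "pairwise")
  expect_true(ct2$p <= 1)
})

test_that("no-prior baseline recovers strong signals and matches g -> Inf", {
  set.seed(14)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- 0.8 * X[, 2] + rnorm(n)
  f0 <- no_prior_baseline(X, y)
  expect_equal(f0$predictors, "x2")
  fg <- best_subset(X, y, g = rep(1e10, 3))
  expect_equal(fg$predictors, f0$predictors)
  expect_equal(fg$beta_tilde, f0$beta_tilde, tolerance = 1e-6)
  f1 <- no_prior_baseline(X[, 1, drop = FALSE], y)
  expect_equal(f1$predictors, "x1")
})

test_that("confidence scores are incremental R-squared", {
  set.seed(15)
  n <- 150
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1.0 * x1 + 0.5 * x2 + rnorm(n)
  fit <- best_subset(cbind(x1 = x1, x2 = x2), y, g = c(5, 5))
  cs <- confidence_score(fit)
  expect_gt(cs[["x1"]], cs[["x2"]])  # stronger signal scores higher
  expect_true(all(cs >= 0))
  # single-predictor subnet: score equals the fit R-squared
  fit1 <- best_subset(cbind(x1 = x1), y, g = 5)
  expect_equal(unname(confidence_score(fit1)), fit1$r2)
  # orthogonal-to-response predictor given the other: score ~ 0
  y2 <- 1.0 * x1 + rnorm(n)
  q <- qr(cbind(x1, y2))
  x3 <- qr.resid(q, rnorm(n))
  fito <- best_subset(cbind(x1 = x1, x3 = x3), y2, g = c(5, 5))
  if (all(c("x1", "x3") %in% fito$predictors)) {
    expect_lt(confidence_score(fito)[["x3"]], 1e-6)
  }
})

test_that("mu tuning ties resolve to the smallest mu; one p is its own meta", {
  set.seed(16)
  n <- 80
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  Y <- matrix(3 * X[, 1] + 0.3 * rnorm(n), dimnames = list(NULL, "y1"))
  r <- matrix(1, 2, 1, dimnames = list(c("x1", "x2"), "y1"))
  tm <- tune_mu(X, Y, r, mu_grid = c(0, 0.5, 1, 2), B = 99, seed = 3)
  # the dominant signal is selected at every mu, so the profile is flat and
  # the tie resolves to the smallest mu
  expect_equal(length(unique(tm$profile$meta_p)), 1)
  expect_equal(tm$mu, 0)
  # Fisher's method with a single p-value returns that p-value (df = 2)
  p1 <- tm$fits$y1$correlation_p
  expect_equal(tm$profile$meta_p[1], p1, tolerance = 1e-12)
  expect_error(tune_mu(X, Y, r, mu_grid = numeric(0)), "nonempty")
})

test_that("subnetwork tables round-trip through writers", {
  set.seed(17)
  n <- 60
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  Y <- cbind(y1 = 2 * X[, 1] + 0.5 * rnorm(n), y2 = rnorm(n))
  r <- matrix(1, 2, 2, dimnames = list(colnames(X), colnames(Y)))
  fits <- fit_subnetworks(X, Y, r, mu = 1, B = 99, seed = 4)
  expect_named(fits, c("y1", "y2"))
  expect_true(fits$y1$kept)
  tj <- tempfile(fileext = ".json"); tt <- tempfile(fileext = ".tsv")
  tab <- write_subnetworks(fits, json_path = tj, tsv_path = tt)
  expect_true(file.exists(tj) && file.exists(tt))
  back <- utils::read.delim(tt)
  expect_equal(nrow(back), nrow(tab))
  js <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(nrow(js), 2L)
})
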