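test_that("full-rank PLS reproduces least squares", {
  for (seed in 1:10) {
    inst <- random_instance(20, 5, seed)
    fit <- fit_pls(inst$X, inst$y, ncomp = 5)
    oracle <- ols_oracle(inst$X, inst$y)
    expect_equal(unname(fit$coefficients), oracle[-1], tolerance = 1e-6)
    expect_equal(fit$intercept, oracle[1], tolerance = 1e-6)
  }
})

test_that("single-column PLS equals simple regression on autoscaled data", {
  set.seed(2)
  x <- matrix(rnorm(30), dimnames = list(NULL, "v"))
  y <- 2.5 * x[, 1] + rnorm(30, sd = 0.2)
  fit <- fit_pls(x, y, ncomp = 1)
  slope <- cov(x[, 1], y) / var(x[, 1])
  expect_equal(unname(fit$coefficients), slope, tolerance = 1e-8)
})

test_that("noiseless linear y gives perfect fit and perfect LOO", {
  set.seed(3)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X %*% c(1, -2, 0.5)) + 4
  fit <- fit_pls(X, y, ncomp = 3)
  r2 <- sum((fit$fitted - mean(y))^2) / sum((y - mean(y))^2)
  expect_equal(r2, 1, tolerance = 1e-8)
  expect_equal(loo_q2(X, y, 3)$q2, 1, tolerance = 1e-6)
})

test_that("X-scores from NIPALS are mutually orthogonal", {
  inst <- random_instance(25, 8, 4)
  fit <- fit_pls(inst$X, inst$y, ncomp = 5)
  G <- crossprod(fit$scores)
  expect_equal(G - diag(diag(G)), matrix(0, 5, 5), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("fit_pls rejects bad inputs with informative errors", {
  inst <- random_instance(10, 4, 5)
  expect_error(fit_pls(inst$X, rep(1, 10), ncomp = 2), "constant")
  expect_error(fit_pls(inst$X, inst$y, ncomp = 9), "achievable rank")
  expect_error(loo_q2(inst$X[1:2, ], inst$y[1:2], 1), "n >= 3")
  expect_error(loo_q2(inst$X, inst$y, ncomp = 9), "too large")
})

test_that("loo_q2 equals a naive refit loop exactly", {
  inst <- random_instance(15, 6, 6)
  got <- loo_q2(inst$X, inst$y, ncomp = 3)
  pred <- vapply(seq_along(inst$y), function(i) {
    f <- fit_pls(inst$X[-i, ], inst$y[-i], ncomp = 3)
    predict(f, inst$X[i, , drop = FALSE])
  }, numeric(1))
  expect_identical(got$predictions, pred)
  expect_equal(got$press, sum((inst$y - pred)^2))
  expect_equal(got$q2, 1 - got$press / sum((inst$y - mean(inst$y))^2))
})

test_that("permutation null gives mean Q2 near or below zero", {
  set.seed(8)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rnorm(20)
  q2s <- replicate(200, loo_q2(X, sample(y), ncomp = 2)$q2)
  expect_lte(mean(q2s), 0.05)
})

test_that("component selection maximises Q2 with ties to the smaller model", {
  # one latent factor: the first component carries all the signal
  set.seed(9)
  t1 <- rnorm(20)
  X <- outer(t1, rnorm(6)) + matrix(rnorm(120, sd = 0.3), 20, 6)
  y <- t1 + rnorm(20, sd = 0.3)
  sel <- select_components(X, y, ncomp_max = 4)
  expect_equal(sel$ncomp, 1)
  expect_equal(sel$q2, max(sel$profile$q2))

  # exact tie (rank-1 X degenerates at the second component) -> smaller A
  x1 <- rnorm(15)
  X1 <- cbind(a = x1, b = x1)
  yt <- x1 + rnorm(15, sd = 0.2)
  selt <- select_components(X1, yt, ncomp_max = 2)
  expect_equal(selt$ncomp, 1)

  # pure noise: best Q2 <= 0 and the caller is warned
  set.seed(123)
  Xn <- matrix(rnorm(30 * 5), 30, 5)
  yn <- rnorm(30)
  expect_warning(seln <- select_components(Xn, yn, ncomp_max = 3),
                 "no predictive signal")
  expect_lte(seln$q2, 0)
})

test_that("FFD retains seeded informative variables and is deterministic", {
  set.seed(20)
  ok <- logical(20)
  for (r in 1:20) {
    n <- 30; V <- 32
    X <- matrix(abs(rnorm(n * V)), n, V, dimnames = list(NULL, sprintf("v%d", 1:V)))
    y <- 2 * X[, 1] - 1.5 * X[, 2] + rnorm(n, sd = 0.3)
    f <- ffd_select(X, y, ncomp = 2, seed = 1000 + r)
    ok[r] <- all(c("v1", "v2") %in% f$retained)
  }
  expect_gte(mean(ok), 0.95)

  # determinism: same seed, same selection; duplicate columns with identical
  # design columns share their fate by construction
  inst <- random_instance(20, 10, 30)
  y <- inst$y
  f1 <- ffd_select(inst$X, y, ncomp = 2, seed = 7)
  f2 <- ffd_select(inst$X, y, ncomp = 2, seed = 7)
  expect_identical(f1$retained, f2$retained)
  expect_identical(f1$effects, f2$effects)
})

test_that("FFD noise retention approaches ~0.5 for large designs", {
  # dummies estimate only design noise; with enough runs that noise
  # averages out and a pure-noise variable is kept iff its (symmetric)
  # causal effect is below the 2-SD dummy threshold -> retention ~ 0.5
  set.seed(21)
  res <- replicate(4, {
    n <- 24; V <- 16
    X <- matrix(abs(rnorm(n * V)), n, V, dimnames = list(NULL, sprintf("v%d", 1:V)))
    f <- ffd_select(X, rnorm(n), ncomp = 2, n_runs = 1200,
                    seed = sample.int(1e6, 1))
    length(f$retained) / V
  })
  expect_lte(mean(res), 0.65)
})

test_that("FFD input contracts", {
  inst <- random_instance(12, 10, 40)
  expect_error(ffd_select(inst$X, inst$y, ncomp = 2, n_runs = 5, seed = 1),
               "cannot resolve")
  expect_error(ffd_select(inst$X[, 1:4], inst$y, ncomp = 1, seed = 1),
               "at least 8")
})
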