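test_that("internal validation reproduces the printed formulas on hand vectors", {
  # perfect fit
  r <- internal_validation(c(1, 2, 3), c(1, 2, 3), press = 0)
  expect_equal(r$r2, 1)
  expect_equal(r$press, 0)
  expect_equal(r$rmsee, 0)
  # PRESS/RMSEE arithmetic: e = (0.1, -0.1, 0)
  press <- sum(c(0.1, -0.1, 0)^2)
  r2 <- internal_validation(c(1, 2, 3), c(1, 2, 3), press = press)
  expect_equal(r2$press, 0.02)
  expect_equal(r2$rmsee, sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(r2$q2, 1 - 0.02 / 2)
  # R2 as the ratio of explained to total sum of squares
  r3 <- internal_validation(c(1, 2, 3), c(1.1, 2.0, 2.9), press = 0.1)
  expect_equal(r3$r2, 1.62 / 2)
  expect_error(internal_validation(c(2, 2, 2), c(2, 2, 2), 0), "zero variance")
})

test_that("external validation: identity, null model and swap symmetry", {
  y <- c(4.1, 5.3, 6.2, 7.4, 8.0, 5.9)
  r <- external_validation(y, y, ybar_train = 6)
  expect_equal(r$r2pred, 1)
  expect_equal(r$rm2, 1)
  expect_equal(r$rm2_prime, 1)
  expect_equal(r$rm2_delta, 0)
  expect_equal(r$k_prime, 1)

  # constant prediction at the training mean: R2pred = 0 by construction
  r0 <- external_validation(y, rep(6, 6) + c(1e-9, -1e-9, 0, 0, 0, 0), 6)
  expect_equal(r0$r2pred, 0, tolerance = 1e-6)

  # swapping observed and predicted swaps rm2 and rm2' exactly
  set.seed(12)
  yhat <- y + rnorm(6, sd = 0.5)
  a <- external_validation(y, yhat, 6)
  b <- external_validation(yhat, y, 6)
  expect_identical(a$rm2, b$rm2_prime)
  expect_identical(a$rm2_prime, b$rm2)
  expect_identical(a$k, b$k_prime)
})

test_that("external metrics match an independent scripted recomputation", {
  y <- c(5.2, 6.8, 4.9, 7.7, 6.1, 5.6)
  yhat <- c(5.5, 6.4, 5.2, 7.2, 6.5, 5.1)
  ybar_tr <- 6.0
  got <- external_validation(y, yhat, ybar_tr)
  # second implementation, written straight from the formulas
  r2 <- cor(y, yhat)^2
  k <- sum(y * yhat) / sum(yhat^2)
  kp <- sum(y * yhat) / sum(y^2)
  r02 <- 1 - sum((y - k * yhat)^2) / sum((y - mean(y))^2)
  r02p <- 1 - sum((yhat - kp * y)^2) / sum((yhat - mean(yhat))^2)
  expect_equal(got$r2pred, 1 - sum((y - yhat)^2) / sum((y - ybar_tr)^2))
  expect_equal(got$rmsep, sqrt(mean((y - yhat)^2)))
  expect_equal(got$r2_test, r2)
  expect_equal(got$k, k)
  expect_equal(got$k_prime, kp)
  expect_equal(got$rm2, r2 * (1 - sqrt(r2 - r02)))
  expect_equal(got$rm2_prime, r2 * (1 - sqrt(r2 - r02p)))
  expect_equal(got$rm2_mean, (got$rm2 + got$rm2_prime) / 2)
  expect_equal(got$rm2_delta, abs(got$rm2 - got$rm2_prime))
  expect_equal(got$r2_r02_ratio, (r2 - r02p) / r2)
})

test_that("criteria flags pass on both sets of published reference statistics", {
  rock1 <- list(r2 = 0.914, q2 = 0.59, rmsee = 0.393, r2pred = 0.792,
                rmsep = 0.561, rm2 = 0.759, rm2_prime = 0.573,
                rm2_mean = 0.666, rm2_delta = 0.186, r2_r02_ratio = 0.099,
                k_prime = 0.974)
  f1 <- criteria_flags(rock1)
  expect_true(all(f1$pass))
  expect_true(attr(f1, "valid"))

  rock2 <- list(r2 = 0.933, q2 = 0.54, rmsee = 0.327, r2pred = 0.851,
                rmsep = 0.499, rm2 = 0.753, rm2_prime = 0.616,
                rm2_mean = 0.684, rm2_delta = 0.137, r2_r02_ratio = 0.032,
                k_prime = 0.963)
  f2 <- criteria_flags(rock2)
  expect_true(all(f2$pass))
})

test_that("criteria inequalities are strict at the printed boundaries", {
  base <- list(r2 = 0.95, q2 = 0.6, rmsee = 0.4, r2pred = 0.7, rmsep = 0.5,
               rm2 = 0.6, rm2_prime = 0.6, rm2_mean = 0.6, rm2_delta = 0.1,
               r2_r02_ratio = 0.05, k_prime = 1)
  at <- function(field, value) {
    b <- base; b[[field]] <- value
    f <- criteria_flags(b)
    f$pass[match(c(r2 = "R2", q2 = "Q2_LOO", rm2_delta = "rm2_delta")[field],
                 f$criterion)]
  }
  expect_false(at("q2", 0.5))        # Q2 = 0.5 exactly fails "> 0.5"
  expect_false(at("rm2_delta", 0.2)) # delta = 0.2 exactly fails "< 0.2"
  expect_false(at("r2", 0.9))
  # RMSEP boundary is inclusive (<= 2 RMSEE)
  b <- base; b$rmsep <- 0.8
  expect_true(criteria_flags(b)$pass[4])
})

test_that("leverages match the explicit hat-matrix oracle", {
  set.seed(13)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 6), 20, 6)
    wd <- applicability_domain(X, X, std_residuals = rep(0, 20))
    Xi <- cbind(1, X)
    H <- Xi %*% solve(crossprod(Xi)) %*% t(Xi)
    expect_equal(wd$leverage, unname(diag(H)), tolerance = 1e-8)
    expect_equal(sum(wd$leverage), 6 + 1, tolerance = 1e-8)  # trace = p + 1
  }
})

test_that("h*, centroid leverage and AD flags follow the printed rules", {
  set.seed(14)
  X <- matrix(rnorm(34 * 10), 34, 10)
  ctr <- matrix(colMeans(X), 1)
  wd <- applicability_domain(X, rbind(X, ctr),
                             std_residuals = c(rep(0, 34), NA))
  expect_equal(attr(wd, "h_star"), 3 * 11 / 34)   # ~0.9706
  expect_equal(wd$leverage[35], 1 / 34, tolerance = 1e-10)
  # residual rule: |std residual| > 3 flags a compound even at low leverage
  wd2 <- applicability_domain(X, rbind(X, ctr),
                              std_residuals = c(rep(0, 34), 3.2))
  expect_true(wd2$outside_ad[35])
  expect_false(wd$outside_ad[35])
})

test_that("rank-deficient descriptor spaces fall back to the pseudoinverse", {
  set.seed(15)
  X <- matrix(rnorm(10 * 3), 10, 3)
  X <- cbind(X, X[, 1] + X[, 2])  # exact collinearity
  expect_message(wd <- applicability_domain(X, X, rep(0, 10)),
                 "rank deficient")
  expect_true(all(is.finite(wd$leverage)))
})

test_that("validation JSON serialises a full report", {
  set.seed(16)
  inst <- random_instance(20, 6, 17)
  rownames(inst$X) <- sprintf("c%02d", 1:20)
  act <- tibble::tibble(id = rownames(inst$X), pIC50 = inst$y,
                        cluster = "I")
  split <- make_split(act, n_test = 5, seed = 3)
  itr <- match(split$train, act$id)
  model <- fit_pls(inst$X[itr, ], inst$y[itr], ncomp = 2)
  rep <- validate_model(model, inst$X, inst$y, split)
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$internal$q2, rep$internal$q2, tolerance = 1e-12)
  expect_equal(nrow(back$predictions), 20)
})
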