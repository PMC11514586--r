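scaling_code <- function(scaling = c("autoscale", "none", "pareto")) {
  scaling <- match.arg(scaling)
  c(none = 0L, autoscale = 1L, pareto = 2L)[[scaling]]
}

as_xy <- function(X, y = NULL) {
  if (is.data.frame(X)) {
    X <- descriptor_matrix(as_tibble(X))
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (nrow(X) != length(y)) abort("rows of X must match length of y")
  }
  list(X = X, y = y)
}

x_rank <- function(X, scaling = "autoscale") {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qr(Xc)$rank
}

#' Fit a PLS regression model
#'
#' NIPALS partial least squares with one response (the pIC50 vector).
#' Descriptors are centred and, by default, autoscaled to unit variance;
#' `"pareto"` scaling (square-root of the standard deviation) and `"none"`
#' (centring only) are available. With `ncomp` equal to the rank of the
#' centred descriptor matrix, the fit reproduces least squares.
#'
#' @param X Descriptor tibble (with `id` column) or numeric matrix; rows are
#'   compounds.
#' @param y Numeric response (pIC50), aligned with the rows of `X`.
#' @param ncomp Number of latent variables (>= 1, <= rank of centred `X`).
#' @param scaling `"autoscale"` (default), `"pareto"` or `"none"`.
#' @return A `grind_pls` object: coefficients in original descriptor units,
#'   intercept, NIPALS weights/loadings/scores, preprocessing constants,
#'   training ids and metadata.
#' @export
fit_pls <- function(X, y, ncomp, scaling = c("autoscale", "none", "pareto")) {
  scaling <- match.arg(scaling)
  meta <- attr(X, "meta")
  xy <- as_xy(X, y)
  if (ncomp < 1) abort("ncomp must be >= 1")
  if (var(xy$y) < 1e-12) abort("y is constant; nothing to regress")
  rk <- x_rank(xy$X)
  if (ncomp > rk)
    abort(sprintf("ncomp = %d exceeds the rank of centred X (achievable rank %d)",
                  ncomp, rk))
  fit <- cpp_pls_fit(xy$X, xy$y, as.integer(ncomp), scaling_code(scaling))
  structure(list(
    coefficients = setNames(as.numeric(fit$coefficients), colnames(xy$X)),
    intercept = fit$intercept,
    coef_scaled = setNames(as.numeric(fit$coef_scaled), colnames(xy$X)),
    weights = fit$weights, loadings = fit$loadings,
    y_loadings = as.numeric(fit$y_loadings), scores = fit$scores,
    ncomp = fit$ncomp_used, scaling = scaling,
    x_means = as.numeric(fit$x_means), x_scales = as.numeric(fit$x_scales),
    y_mean = fit$y_mean,
    fitted = as.numeric(fit$fitted), y = xy$y,
    train_ids = rownames(xy$X), variables = colnames(xy$X), meta = meta
  ), class = "grind_pls")
}

#' @export
print.grind_pls <- function(x, ...) {
  r2 <- sum((x$fitted - mean(x$y))^2) / sum((x$y - mean(x$y))^2)
  cat(sprintf("<PLS model: %d latent variables, %d descriptors, n = %d, R2 = %.3f>\n",
              x$ncomp, length(x$coefficients), length(x$y), r2))
  invisible(x)
}

#' Predict activities from a PLS model
#'
#' @param object A `grind_pls` model.
#' @param newdata Descriptor tibble or matrix whose columns match the model
#'   variables (by name when named).
#' @param ... Unused.
#' @return Numeric vector of predicted pIC50 values.
#' @export
predict.grind_pls <- function(object, newdata, ...) {
  X <- as_xy(newdata)$X
  if (!is.null(colnames(X))) {
    missing <- setdiff(object$variables, colnames(X))
    if (length(missing) > 0)
      abort(sprintf("newdata is missing %d model variable(s): %s%s",
                    length(missing), paste(head(missing, 5), collapse = ", "),
                    if (length(missing) > 5) ", ..." else ""))
    X <- X[, object$variables, drop = FALSE]
  } else if (ncol(X) != length(object$coefficients)) {
    abort("newdata has wrong number of columns and no column names")
  }
  as.numeric(X %*% object$coefficients + object$intercept)
}

#' @rdname fit_pls
#' @param x A `grind_pls` model (for `tidy`).
#' @param ... Unused.
#' @export
tidy.grind_pls <- function(x, ...) {
  tb <- tibble(term = x$variables, estimate = unname(x$coefficients),
               estimate_scaled = unname(x$coef_scaled))
  if (!is.null(x$meta)) tb <- left_join(tb, x$meta, by = c(term = "name"))
  tb
}

#' @rdname fit_pls
#' @export
glance.grind_pls <- function(x, ...) {
  tss <- sum((x$y - mean(x$y))^2)
  tibble(
    r.squared = sum((x$fitted - mean(x$y))^2) / tss,
    rmse_fit = sqrt(mean((x$y - x$fitted)^2)),
    ncomp = x$ncomp, nobs = length(x$y), n_vars = length(x$coefficients),
    scaling = x$scaling
  )
}

#' Leave-one-out cross-validation
#'
#' Removes each training compound in turn, refits the PLS model from
#' scratch on the remaining n - 1 compounds (no deflation shortcuts) and
#' predicts the held-out activity. `PRESS` is the sum of squared held-out
#' errors; `Q2 = 1 - PRESS / sum((y - mean(y))^2)` with the full training
#' mean, as in the printed definition.
#'
#' @inheritParams fit_pls
#' @return List with `q2`, `press`, `predictions` (held-out, in row order)
#'   and `sdep = sqrt(PRESS/n)`.
#' @export
loo_q2 <- function(X, y, ncomp, scaling = c("autoscale", "none", "pareto")) {
  scaling <- match.arg(scaling)
  xy <- as_xy(X, y)
  n <- nrow(xy$X)
  if (n < 3) abort("leave-one-out needs n >= 3")
  if (ncomp >= n - 1)
    abort(sprintf("ncomp = %d too large for LOO with n = %d (need ncomp < n - 1)",
                  ncomp, n))
  # literal naive loop: refit on each fold's n-1 rows, predict the held-out
  # row with the same arithmetic predict() uses
  code <- scaling_code(scaling)
  pred <- vapply(seq_len(n), function(i) {
    f <- cpp_pls_fit(xy$X[-i, , drop = FALSE], xy$y[-i], as.integer(ncomp), code)
    as.numeric(xy$X[i, , drop = FALSE] %*% as.numeric(f$coefficients) + f$intercept)
  }, numeric(1))
  press <- sum((xy$y - pred)^2)
  tss <- sum((xy$y - mean(xy$y))^2)
  list(q2 = 1 - press / tss, press = press, predictions = pred,
       sdep = sqrt(press / n))
}

#' Choose the number of latent variables by LOO Q2
#'
#' Evaluates `Q2_LOO` for 1..`ncomp_max` components and returns the
#' maximiser; ties go to the smaller model. Warns when even the best model
#' has `Q2 <= 0` (no predictive signal).
#'
#' @inheritParams fit_pls
#' @param ncomp_max Largest number of components to try (capped at the rank
#'   of centred `X` and at n - 2).
#' @return List with `ncomp` (the selected A), `q2` (its Q2) and `profile`
#'   (tibble of Q2 by ncomp).
#' @export
select_components <- function(X, y, ncomp_max = 10,
                              scaling = c("autoscale", "none", "pareto")) {
  scaling <- match.arg(scaling)
  xy <- as_xy(X, y)
  amax <- min(ncomp_max, x_rank(xy$X), nrow(xy$X) - 2)
  if (amax < 1) abort("no usable components (rank 0 or too few rows)")
  q2 <- map_dbl(seq_len(amax), function(a)
    loo_q2(xy$X, xy$y, a, scaling = scaling)$q2)
  best <- which.max(q2)  # ties resolve to the smaller A
  if (q2[best] <= 0)
    warn(sprintf("best LOO Q2 is %.3f <= 0: the model has no predictive signal",
                 q2[best]))
  list(ncomp = best, q2 = q2[best],
       profile = tibble(ncomp = seq_len(amax), q2 = q2))
}
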