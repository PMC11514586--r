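#' Internal validation statistics
#'
#' Training-set statistics in their printed literal forms:
#' `R2 = sum((yhat - ybar)^2) / sum((y - ybar)^2)` on fitted values,
#' `PRESS = sum(e_i^2)` over held-out LOO errors, `Q2 = 1 - PRESS/TSS`,
#' and `RMSEE = sqrt(PRESS/n)`. Because that RMSEE definition is built on
#' PRESS (i.e. it is an SDEP), the conventional fitted-residual error is
#' also reported separately as `rmse_fit`.
#'
#' @param y_train Observed training activities.
#' @param yhat_train Fitted training activities.
#' @param press LOO predictive residual sum of squares (from [loo_q2()]).
#' @return One-row tibble: `n_train`, `r2`, `press`, `q2`, `rmsee`,
#'   `rmse_fit`.
#' @export
internal_validation <- function(y_train, yhat_train, press) {
  if (length(y_train) != length(yhat_train)) abort("vectors must align")
  n <- length(y_train)
  if (n < 3) abort("internal validation needs n >= 3")
  ybar <- mean(y_train)
  tss <- sum((y_train - ybar)^2)
  if (tss < 1e-12) abort("zero variance in y_train")
  tibble(
    n_train = n,
    r2 = sum((yhat_train - ybar)^2) / tss,
    press = press,
    q2 = 1 - press / tss,
    rmsee = sqrt(press / n),
    rmse_fit = sqrt(mean((y_train - yhat_train)^2))
  )
}

#' External validation statistics
#'
#' Test-set statistics: `R2pred = 1 - sum((y - yhat)^2) / sum((y -
#' ybar_train)^2)` (deviations measured against the *training* mean),
#' `RMSEP = sqrt(sum((y - yhat)^2) / n_test)`, and the rm2 metric family
#' from the observed-vs-predicted regressions through the origin
#' (Golbraikh-Tropsha): with `k = sum(y yhat)/sum(yhat^2)` and `k' = sum(y
#' yhat)/sum(y^2)`,
#' `r0^2 = 1 - sum((y - k yhat)^2)/sum((y - ybar)^2)` and `r0'^2` with the
#' axes swapped, then `rm2 = r2 (1 - sqrt(r2 - r0^2))` and `rm2' = r2 (1 -
#' sqrt(r2 - r0'^2))`. A numerically negative radicand (r2 < r0^2) is
#' clamped at zero with a message. Swapping observed and predicted swaps
#' `rm2` and `rm2'` exactly.
#'
#' @param y_test Observed test activities.
#' @param yhat_test Predicted test activities.
#' @param ybar_train Mean activity of the training set.
#' @return One-row tibble: `n_test`, `r2pred`, `rmsep`, `r2_test`
#'   (squared Pearson correlation of observed and predicted), `k`,
#'   `k_prime`, `r02`, `r02_prime`, `rm2`, `rm2_prime`, `rm2_mean`,
#'   `rm2_delta`, `r2_r02_ratio` (`(r2 - r02')/r2`), `r2_r02_ratio_alt`
#'   (`(r2 - r02)/r2`; both axis orientations are reported).
#' @export
external_validation <- function(y_test, yhat_test, ybar_train) {
  if (length(y_test) != length(yhat_test)) abort("vectors must align")
  n <- length(y_test)
  if (n < 3) abort("external validation needs n >= 3")
  sse <- sum((y_test - yhat_test)^2)
  r2pred <- 1 - sse / sum((y_test - ybar_train)^2)
  rmsep <- sqrt(sse / n)
  r2 <- cor(y_test, yhat_test)^2
  k <- sum(y_test * yhat_test) / sum(yhat_test^2)
  k_prime <- sum(y_test * yhat_test) / sum(y_test^2)
  r02 <- 1 - sum((y_test - k * yhat_test)^2) / sum((y_test - mean(y_test))^2)
  r02p <- 1 - sum((yhat_test - k_prime * y_test)^2) /
    sum((yhat_test - mean(yhat_test))^2)
  rm2 <- r2 * (1 - sqrt(clamp0(r2 - r02)))
  rm2p <- r2 * (1 - sqrt(clamp0(r2 - r02p)))
  tibble(
    n_test = n, r2pred = r2pred, rmsep = rmsep, r2_test = r2,
    k = k, k_prime = k_prime, r02 = r02, r02_prime = r02p,
    rm2 = rm2, rm2_prime = rm2p,
    rm2_mean = (rm2 + rm2p) / 2,
    rm2_delta = abs(rm2 - rm2p),
    r2_r02_ratio = (r2 - r02p) / r2,
    r2_r02_ratio_alt = (r2 - r02) / r2
  )
}

clamp0 <- function(x) {
  if (x < 0) {
    inform(sprintf("rm2 radicand %.3g < 0 clamped to 0 (r2 < r0^2)", x))
    0
  } else x
}

#' Acceptance criteria flags
#'
#' Evaluates the model-quality criteria exactly as printed (all
#' inequalities strict except the k' band): R2 > 0.9, Q2 > 0.5, R2pred >
#' 0.6, RMSEP <= 2 RMSEE, rm2 > 0.5, rm2' > 0.5, mean rm2 > 0.5, delta rm2
#' < 0.2, (r2 - r0'^2)/r2 < 0.1, 0.85 <= k' <= 1.15. The model is declared
#' valid only when every flag passes.
#'
#' @param report One-row tibble (or list) holding the fields produced by
#'   [internal_validation()] and [external_validation()].
#' @return Tibble with columns `criterion`, `value`, `requirement`, `pass`;
#'   attribute `"valid"` is the conjunction.
#' @export
criteria_flags <- function(report) {
  report <- as.list(report)
  need <- c("r2", "q2", "r2pred", "rmsep", "rmsee", "rm2", "rm2_prime",
            "rm2_mean", "rm2_delta", "r2_r02_ratio", "k_prime")
  missing <- setdiff(need, names(report))
  if (length(missing) > 0)
    abort(sprintf("report is missing: %s", paste(missing, collapse = ", ")))
  flags <- tibble(
    criterion = c("R2", "Q2_LOO", "R2_pred", "RMSEP", "rm2", "rm2_prime",
                  "rm2_mean", "rm2_delta", "(r2-r0'2)/r2", "k_prime"),
    value = c(report$r2, report$q2, report$r2pred, report$rmsep, report$rm2,
              report$rm2_prime, report$rm2_mean, report$rm2_delta,
              report$r2_r02_ratio, report$k_prime),
    requirement = c("> 0.9", "> 0.5", "> 0.6", "<= 2 RMSEE", "> 0.5", "> 0.5",
                    "> 0.5", "< 0.2", "< 0.1", "0.85 <= k' <= 1.15"),
    pass = c(report$r2 > 0.9,
             report$q2 > 0.5,
             report$r2pred > 0.6,
             report$rmsep <= 2 * report$rmsee,
             report$rm2 > 0.5,
             report$rm2_prime > 0.5,
             report$rm2_mean > 0.5,
             report$rm2_delta < 0.2,
             report$r2_r02_ratio < 0.1,
             report$k_prime >= 0.85 & report$k_prime <= 1.15)
  )
  attr(flags, "valid") <- all(flags$pass)
  flags
}

#' Full validation report for a fitted model and split
#'
#' Convenience wrapper joining [internal_validation()],
#' [external_validation()], [criteria_flags()] and the applicability domain
#' into one object.
#'
#' @param model A `grind_pls` model fitted on the training rows.
#' @param X Descriptor tibble/matrix for all compounds (training variables).
#' @param y Activities aligned with `X` rows.
#' @param split A `grind_split`.
#' @param loo Result of [loo_q2()] on the training rows (recomputed when
#'   omitted).
#' @param scaling Scaling used for the model (for the LOO recomputation).
#' @return A `validation_report`: list with `internal`, `external`, `flags`,
#'   `valid`, `williams` (see [applicability_domain()]) and `predictions`.
#' @export
validate_model <- function(model, X, y, split, loo = NULL,
                           scaling = model$scaling) {
  xy <- as_xy(X, y)
  ids <- rownames(xy$X)
  if (is.null(ids)) abort("X must carry compound ids (rownames or id column)")
  itr <- match(split$train, ids)
  ite <- match(split$test, ids)
  if (anyNA(itr) || anyNA(ite)) abort("split ids not found in X")
  Xtr <- xy$X[itr, model$variables, drop = FALSE]
  if (is.null(loo)) loo <- loo_q2(Xtr, xy$y[itr], model$ncomp, scaling = scaling)
  yhat_tr <- predict(model, Xtr)
  internal <- internal_validation(xy$y[itr], yhat_tr, loo$press)
  yhat_te <- predict(model, xy$X[ite, model$variables, drop = FALSE])
  external <- external_validation(xy$y[ite], yhat_te, mean(xy$y[itr]))
  rep_row <- bind_cols(internal, external)
  flags <- criteria_flags(rep_row)
  preds <- tibble(
    id = c(ids[itr], ids[ite]),
    set = rep(c("train", "test"), c(length(itr), length(ite))),
    observed = c(xy$y[itr], xy$y[ite]),
    predicted = c(yhat_tr, yhat_te)
  )
  williams <- applicability_domain(
    Xtr, xy$X[c(itr, ite), model$variables, drop = FALSE],
    std_residuals = (preds$observed - preds$predicted) / internal$rmsee,
    ids = preds$id, set = preds$set)
  structure(list(internal = internal, external = external, flags = flags,
                 valid = attr(flags, "valid"), williams = williams,
                 predictions = preds),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Internal validation\n")
  print(as.data.frame(x$internal), row.names = FALSE, digits = 4)
  cat("External validation\n")
  print(as.data.frame(x$external), row.names = FALSE, digits = 4)
  cat("Criteria\n")
  print(as.data.frame(x$flags), row.names = FALSE, digits = 4)
  cat(sprintf("Model %s\n", if (x$valid) "VALID (all criteria pass)"
              else "NOT valid (some criteria fail)"))
  out <- attr(x$williams, "outliers")
  if (length(out) > 0)
    cat("Outside applicability domain:", paste(out, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a validation report to JSON
#' @param report A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(list(
    internal = report$internal, external = report$external,
    criteria = report$flags, valid = report$valid,
    williams = report$williams,
    h_star = attr(report$williams, "h_star"),
    predictions = report$predictions
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
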