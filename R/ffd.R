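#' Fractional-factorial-design variable selection
#'
#' GOLPE-style FFD: a two-level design (+1 keep / -1 drop) over the real
#' descriptor variables plus `ceiling(dummy_fraction * V)` dummy variables.
#' For every design row a PLS model is fitted on the kept subset and scored
#' by its leave-one-out `SDEP = sqrt(PRESS/n)`. The effect of a variable is
#' the mean SDEP of runs keeping it minus the mean SDEP of runs dropping
#' it: positive means keeping the variable worsens prediction. Dummies are
#' fictitious (they never enter a fit), so their effects estimate the noise
#' level of the effect statistic; a real variable is dropped when its
#' effect exceeds `mean + 2 SD` of the dummy effects.
#'
#' Variables that are zero across all training rows are removed before the
#' design is built (they carry no information). The design is a fold-over
#' of random balanced +-1 rows, deterministic given `seed`.
#'
#' @inheritParams fit_pls
#' @param ncomp Latent variables used in every design-run fit.
#' @param dummy_fraction Dummies as a fraction of the number of real
#'   variables (default 0.2).
#' @param n_runs Number of design rows (even; default `2 * (V + dummies)`,
#'   at least `V + 1` as required for resolution).
#' @param seed Integer seed for the design (required: the run is stochastic).
#' @return List with `retained` (variable names), `retained_idx` (indices
#'   into the columns of `X`), `effects` tibble (variable, effect, dummy
#'   flag), `threshold`, and `n_runs`.
#' @export
ffd_select <- function(X, y, ncomp, dummy_fraction = 0.2, n_runs = NULL,
                       seed, scaling = c("autoscale", "none", "pareto")) {
  scaling <- match.arg(scaling)
  xy <- as_xy(X, y)
  Xm <- xy$X
  if (is.null(colnames(Xm))) colnames(Xm) <- sprintf("V%d", seq_len(ncol(Xm)))
  nonzero <- which(apply(Xm, 2, function(col) any(col != 0)))
  informative <- nonzero[apply(Xm[, nonzero, drop = FALSE], 2, sd) > 0]
  V <- length(informative)
  if (V < 8) abort("FFD selection needs at least 8 informative variables")
  ndum <- ceiling(dummy_fraction * V)
  m <- V + ndum
  if (is.null(n_runs)) n_runs <- 2L * m
  if (n_runs < V + 1)
    abort(sprintf("n_runs = %d cannot resolve %d variables (need >= %d)",
                  n_runs, V, V + 1))
  if (missing(seed)) abort("seed is required: the FFD design is randomised")
  set.seed(as.integer(seed))
  half <- ceiling(n_runs / 2)
  D <- matrix(sample(c(-1, 1), half * m, replace = TRUE), half, m)
  D <- rbind(D, -D)[seq_len(2 * half), , drop = FALSE]  # fold-over
  n_runs <- nrow(D)

  Xr <- Xm[, informative, drop = FALSE]
  sdep <- map_dbl(seq_len(n_runs), function(r) {
    keep <- which(D[r, seq_len(V)] > 0)
    if (length(keep) < 2) return(NA_real_)
    a <- min(ncomp, x_rank(Xr[, keep, drop = FALSE]), nrow(Xr) - 2)
    if (a < 1) return(NA_real_)
    # same naive LOO as loo_q2, run inside compiled code for speed
    pred <- cpp_loo_predictions(Xr[, keep, drop = FALSE], xy$y,
                                as.integer(a), scaling_code(scaling))
    sqrt(sum((xy$y - pred)^2) / length(xy$y))
  })
  ok <- is.finite(sdep)
  effect_of <- function(col) {
    kept <- D[, col] > 0
    mean(sdep[kept & ok]) - mean(sdep[!kept & ok])
  }
  eff_real <- map_dbl(seq_len(V), effect_of)
  eff_dummy <- map_dbl(V + seq_len(ndum), effect_of)
  threshold <- mean(eff_dummy) + 2 * sd(eff_dummy)
  drop <- eff_real > threshold
  retained_idx <- informative[!drop]
  list(
    retained = colnames(Xm)[retained_idx],
    retained_idx = unname(retained_idx),
    effects = tibble(
      variable = c(colnames(Xm)[informative], sprintf("dummy%d", seq_len(ndum))),
      effect = c(eff_real, eff_dummy),
      dummy = rep(c(FALSE, TRUE), c(V, ndum))),
    threshold = threshold,
    n_runs = n_runs,
    n_dummies = ndum
  )
}
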