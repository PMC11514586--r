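#' Stratified training/test split
#'
#' Draws a test set of size `n_test` stratified over activity quintiles
#' crossed with structural clusters, so both sets cover the whole pIC50
#' range and every cluster (a 49-compound set with `n_test = 15` gives the
#' 34/15 partition; 47 compounds give 32/15). The compounds with the global
#' minimum and maximum activity are forced into training, so no test
#' compound is extrapolative; singleton clusters go to training with a
#' message.
#'
#' @param activity Tibble with columns `id`, `pIC50` and optionally
#'   `cluster` (as from [read_activity()]).
#' @param n_test Number of test compounds (< n).
#' @param seed Integer seed (the draw within strata is random).
#' @param n_quantiles Number of activity strata (default 5, quintiles).
#' @return A `grind_split`: list with `train` and `test` id vectors, the
#'   annotated `table` (activity tibble with a `set` column) and the
#'   stratification `cells` record.
#' @export
make_split <- function(activity, n_test, seed, n_quantiles = 5) {
  activity <- as_tibble(activity)
  stopifnot(all(c("id", "pIC50") %in% names(activity)))
  n <- nrow(activity)
  if (n_test >= n) abort("n_test must be smaller than the number of compounds")
  if (missing(seed)) abort("seed is required: the split is stochastic")
  set.seed(as.integer(seed))
  cluster <- if ("cluster" %in% names(activity)) activity$cluster else rep("all", n)
  cluster[is.na(cluster)] <- "unclustered"
  br <- unique(quantile(activity$pIC50, probs = seq(0, 1, length.out = n_quantiles + 1)))
  qbin <- cut(activity$pIC50, breaks = br, include.lowest = TRUE, labels = FALSE)
  cell <- paste(cluster, qbin, sep = "/")

  eligible <- rep(TRUE, n)
  eligible[which.min(activity$pIC50)] <- FALSE   # keep activity range in training
  eligible[which.max(activity$pIC50)] <- FALSE
  singletons <- names(which(table(cluster) < 2))
  if (length(singletons) > 0) {
    inform(sprintf("cluster(s) with a single member assigned to training: %s",
                   paste(singletons, collapse = ", ")))
    eligible[cluster %in% singletons] <- FALSE
  }

  # proportional allocation of test slots over cells, largest-remainder
  cells <- tibble(cell = cell, eligible = eligible) |>
    group_by(.data$cell) |>
    summarise(size = n(), n_eligible = sum(.data$eligible), .groups = "drop")
  quota <- n_test * cells$size / n
  take <- pmin(floor(quota), cells$n_eligible)
  rem <- n_test - sum(take)
  if (rem > 0) {
    frac <- quota - floor(quota)
    ord <- order(frac, decreasing = TRUE)
    for (i in ord) {
      if (rem == 0) break
      extra <- min(cells$n_eligible[i] - take[i], 1)
      take[i] <- take[i] + extra
      rem <- rem - extra
    }
    # still short (eligibility limits): top up anywhere possible
    while (rem > 0) {
      room <- which(take < cells$n_eligible)
      if (length(room) == 0) abort("cannot place all test compounds; too few eligible")
      take[room[1]] <- take[room[1]] + 1
      rem <- rem - 1
    }
  }
  test_idx <- integer()
  for (i in seq_len(nrow(cells))) {
    if (take[i] == 0) next
    pool <- which(cell == cells$cell[i] & eligible)
    test_idx <- c(test_idx, pool[sample.int(length(pool), take[i])])
  }
  set <- rep("train", n)
  set[test_idx] <- "test"
  out <- activity
  out$cluster <- cluster
  out$set <- set
  structure(list(
    train = activity$id[set == "train"],
    test = activity$id[set == "test"],
    table = out,
    cells = mutate(cells, n_test = take)
  ), class = "grind_split")
}

#' @export
print.grind_split <- function(x, ...) {
  cat(sprintf("<split: %d train / %d test>\n", length(x$train), length(x$test)))
  print(x$cells)
  invisible(x)
}

#' Principal component scores of a descriptor matrix
#'
#' SVD-based PCA on centred, autoscaled descriptors, used to inspect the
#' spread and clustering of the dataset before splitting.
#'
#' @inheritParams fit_pls
#' @param k Number of components (<= min(n - 1, p)).
#' @return List with `scores` (n x k matrix), `explained` (variance
#'   fractions, non-increasing) and `loadings`.
#' @export
pca_scores <- function(X, k = 2) {
  X <- as_xy(X)$X
  keep <- apply(X, 2, sd) > 0
  Xk <- X[, keep, drop = FALSE]
  kmax <- min(nrow(Xk) - 1, ncol(Xk))
  if (k > kmax) abort(sprintf("k = %d too large (max %d)", k, kmax))
  pc <- prcomp(Xk, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       loadings = pc$rotation[, seq_len(k), drop = FALSE])
}
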