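#' Leverage-based applicability domain (Williams data)
#'
#' Leverage of a compound is its diagonal entry of the hat projection onto
#' the centred space of the model's selected descriptors, plus the
#' intercept term `1/n` (SPSS-style centred leverage, without the `1/n`, is
#' available via `include_intercept = FALSE`). The critical leverage is
#' `h* = 3 (p + 1) / n` with `p` the number of selected variables and `n`
#' the number of training compounds. A compound is outside the
#' applicability domain when its leverage exceeds `h*` or its absolute
#' standardized residual exceeds `residual_limit` (3 by default).
#'
#' A rank-deficient descriptor covariance is handled with the
#' Moore-Penrose pseudoinverse (the effective rank is reported via a
#' message).
#'
#' @param X_train Training descriptor matrix/tibble restricted to the
#'   selected ("key") variables; `p = ncol`.
#' @param X_query Matrix/tibble of compounds to place in the domain
#'   (typically training + test).
#' @param std_residuals Standardized residuals aligned with `X_query` rows
#'   (NA allowed for compounds without observed activity).
#' @param ids Compound ids for `X_query` rows.
#' @param set Optional set labels aligned with `X_query`.
#' @param residual_limit Standardized-residual threshold (default 3).
#' @param include_intercept Add the `1/n` term to leverages (default TRUE).
#' @return Tibble (`williams_data`) with `id`, `set`, `leverage`,
#'   `std_residual`, `outside_ad`; attributes `"h_star"`, `"p"`, `"n"`,
#'   `"outliers"`.
#' @export
applicability_domain <- function(X_train, X_query, std_residuals, ids = NULL,
                                 set = NULL, residual_limit = 3,
                                 include_intercept = TRUE) {
  Xt <- as_xy(X_train)$X
  Xq <- as_xy(X_query)$X
  if (ncol(Xt) != ncol(Xq)) abort("X_train and X_query must share columns")
  n <- nrow(Xt)
  p <- ncol(Xt)
  if (is.null(ids)) ids <- rownames(Xq) %||% sprintf("q%d", seq_len(nrow(Xq)))
  if (is.null(set)) set <- rep(NA_character_, nrow(Xq))
  ctr <- colMeans(Xt)
  Xc <- sweep(Xt, 2, ctr)
  S <- crossprod(Xc)
  sv <- svd(S)
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  rank <- sum(pos)
  if (rank < p)
    inform(sprintf("descriptor covariance is rank deficient (rank %d of %d); pseudoinverse used",
                   rank, p))
  Sinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  Qc <- sweep(Xq, 2, ctr)
  lev <- rowSums((Qc %*% Sinv) * Qc) + if (include_intercept) 1 / n else 0
  h_star <- 3 * (p + 1) / n
  if (length(std_residuals) != nrow(Xq)) abort("std_residuals must align with X_query")
  outside <- lev > h_star | (!is.na(std_residuals) & abs(std_residuals) > residual_limit)
  out <- tibble(id = ids, set = set, leverage = lev,
                std_residual = std_residuals, outside_ad = outside)
  attr(out, "h_star") <- h_star
  attr(out, "p") <- p
  attr(out, "n") <- n
  attr(out, "residual_limit") <- residual_limit
  attr(out, "outliers") <- ids[outside]
  class(out) <- c("williams_data", class(out))
  out
}

#' Williams plot
#'
#' Standardized residual against leverage, with the critical leverage `h*`
#' and the +-3 residual band; points outside the applicability domain are
#' highlighted.
#'
#' @param object A `williams_data` from [applicability_domain()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.williams_data <- function(object, ...) {
  h_star <- attr(object, "h_star")
  rl <- attr(object, "residual_limit") %||% 3
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$leverage, y = .data$std_residual)) +
    ggplot2::geom_hline(yintercept = c(-rl, rl), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = h_star, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$set,
                                     shape = .data$outside_ad)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = "leverage", y = "standardized residual",
                  shape = "outside AD", colour = "set",
                  title = sprintf("Williams plot (h* = %.3f)", h_star)) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
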