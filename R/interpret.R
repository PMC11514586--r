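#' Rank GRIND variables by PLS coefficient
#'
#' Produces the interpretation table: variables sorted by absolute
#' (autoscaled) PLS coefficient, labelled by probe pair and distance range
#' ("DRY-N1: 13.2-13.6 A" style, with an en dash), and marked favourable
#' (positive coefficient: more of the descriptor means higher pIC50) or
#' unfavourable. Exactly-zero coefficients are excluded.
#'
#' @param model A `grind_pls` fitted on a descriptor table carrying
#'   variable metadata (or pass `meta`).
#' @param meta Variable metadata ([variable_meta()]); defaults to the
#'   model's.
#' @param top_n Number of entries (truncated with a warning when larger
#'   than the number of non-zero coefficients).
#' @return Tibble: `rank`, `variable`, `block`, `bin_lo`, `bin_hi`, `label`,
#'   `coefficient` (autoscaled units), `direction`
#'   (favourable/unfavourable).
#' @export
rank_variables <- function(model, meta = model$meta, top_n = 10) {
  coefs <- model$coef_scaled
  tb <- tibble(variable = names(coefs), coefficient = unname(coefs)) |>
    filter(.data$coefficient != 0)
  if (top_n > nrow(tb)) {
    warn(sprintf("top_n = %d exceeds the %d non-zero coefficients; truncated",
                 top_n, nrow(tb)))
    top_n <- nrow(tb)
  }
  if (!is.null(meta)) {
    tb <- left_join(tb, meta[, c("name", "block", "bin_lo", "bin_hi")],
                    by = c(variable = "name"))
  } else {
    tb$block <- NA_character_; tb$bin_lo <- NA_real_; tb$bin_hi <- NA_real_
  }
  tb |>
    arrange(desc(abs(.data$coefficient))) |>
    head(top_n) |>
    mutate(
      rank = row_number(),
      label = ifelse(is.na(.data$block), .data$variable,
                     variable_label(.data$block, .data$bin_lo, .data$bin_hi)),
      direction = ifelse(.data$coefficient > 0, "favourable", "unfavourable")
    ) |>
    select("rank", "variable", "block", "bin_lo", "bin_hi", "label",
           "coefficient", "direction")
}

#' Format a GRIND variable label
#' @param block Block label, e.g. `"DRY-N1"`.
#' @param bin_lo,bin_hi Distance range in Angstrom.
#' @return Character label like `"DRY-N1: 13.2–13.6 Å"`.
#' @export
variable_label <- function(block, bin_lo, bin_hi) {
  sprintf("%s: %g–%g Å", block, bin_lo, bin_hi)
}

#' Convert IC50 to pIC50 and back
#'
#' `pIC50 = -log10(IC50 in mol/L)`. The `unit` argument accepts molar
#' prefixes so assay tables in micromolar can be converted directly.
#'
#' @param ic50 IC50 value(s), > 0.
#' @param unit One of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"` (default `"M"`).
#' @return pIC50 value(s).
#' @export
ic50_to_pic50 <- function(ic50, unit = c("M", "mM", "uM", "nM", "pM")) {
  unit <- match.arg(unit)
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    abort("IC50 must be positive and finite")
  fac <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[unit]]
  -log10(ic50 * fac)
}

#' @rdname ic50_to_pic50
#' @param pic50 pIC50 value(s).
#' @return IC50 in the requested unit.
#' @export
pic50_to_ic50 <- function(pic50, unit = c("M", "mM", "uM", "nM", "pM")) {
  unit <- match.arg(unit)
  fac <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[unit]]
  10^(-pic50) / fac
}

#' Prediction residual table
#'
#' Per-compound bookkeeping table in the conventional report layout:
#' predicted pIC50, experimental pIC50 and the residual `experimental -
#' predicted`. Rounding (2 decimals) happens only here, at the report
#' layer.
#'
#' @param predicted Predicted pIC50 values.
#' @param observed Experimental pIC50 values.
#' @param ids Optional compound ids.
#' @param digits Decimal places for the report (default 2; `NA` = no
#'   rounding).
#' @return Tibble: `id`, `pic50_pred`, `pic50_exp`, `residual`.
#' @export
residual_table <- function(predicted, observed, ids = NULL, digits = 2) {
  if (length(predicted) != length(observed)) abort("vectors must align")
  if (is.null(ids)) ids <- sprintf("cpd_%d", seq_along(predicted))
  rnd <- function(x) if (is.na(digits)) x else round(x, digits)
  tibble(id = ids,
         pic50_pred = rnd(predicted),
         pic50_exp = rnd(observed),
         residual = rnd(rnd(observed) - rnd(predicted)))
}

#' Predict with applicability-domain annotation
#'
#' Predicts activities for new compounds and flags whether each lies inside
#' the model's applicability domain (leverage vs `h*`; residual criterion
#' does not apply to unobserved compounds).
#'
#' @param model A `grind_pls` model.
#' @param X_new Descriptor tibble/matrix for the new compounds.
#' @param X_train Training descriptors on the model variables (for the
#'   leverage computation).
#' @return Tibble: `id`, `predicted`, `leverage`, `in_ad`.
#' @export
predict_with_ad <- function(model, X_new, X_train) {
  Xn <- as_xy(X_new)$X[, model$variables, drop = FALSE]
  Xt <- as_xy(X_train)$X[, model$variables, drop = FALSE]
  pred <- predict(model, Xn)
  wd <- applicability_domain(Xt, Xn, std_residuals = rep(NA_real_, nrow(Xn)),
                             ids = rownames(Xn) %||% sprintf("new_%d", seq_len(nrow(Xn))))
  tibble(id = wd$id, predicted = pred, leverage = wd$leverage,
         in_ad = !wd$outside_ad)
}
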