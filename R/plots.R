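#' Observed vs predicted activity plot
#'
#' @param object A `grind_pipeline` result from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grind_pipeline <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                   colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "experimental pIC50", y = "predicted pIC50") +
    ggplot2::theme_minimal()
}

#' Correlogram profile plot
#'
#' Descriptor value against bin distance, one panel per probe-pair block,
#' for one or a few compounds.
#'
#' @param desc Descriptor tibble from [grind_descriptors()].
#' @param ids Compound ids to show (default: first compound).
#' @return A ggplot object.
#' @export
plot_correlogram <- function(desc, ids = desc$id[1]) {
  meta <- attr(desc, "meta")
  if (is.null(meta)) abort("descriptor tibble lacks variable metadata")
  df <- desc |>
    filter(.data$id %in% ids) |>
    tidyr::pivot_longer(-"id", names_to = "name", values_to = "value") |>
    left_join(meta, by = "name")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lo, y = .data$value,
                                   colour = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~block, scales = "free_y") +
    ggplot2::labs(x = "node-pair distance (Å)",
                  y = "max energy product (kcal²/mol²)") +
    ggplot2::theme_minimal()
}

#' PLS coefficient plot
#'
#' Autoscaled PLS coefficients by variable index, coloured by probe-pair
#' block - the plot used to read off which distance bins drive activity.
#'
#' @param model A `grind_pls` with variable metadata.
#' @param top_n Highlight the strongest `top_n` variables.
#' @return A ggplot object.
#' @export
plot_coefficients <- function(model, top_n = 10) {
  tb <- tidy(model)
  if (!"block" %in% names(tb)) abort("model lacks variable metadata")
  lab <- rank_variables(model, top_n = top_n)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$index, y = .data$estimate_scaled,
                                   fill = .data$block)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(data = left_join(lab, tb[, c("term", "index")],
                                        by = c(variable = "term")),
                       ggplot2::aes(x = .data$index, y = .data$coefficient,
                                    label = .data$variable),
                       inherit.aes = FALSE, size = 2, angle = 90,
                       hjust = "outward") +
    ggplot2::labs(x = "GRIND variable index", y = "PLS coefficient (autoscaled)") +
    ggplot2::theme_minimal()
}
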