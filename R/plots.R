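#' Effect-size heatmap for a pipeline run
#'
#' Plots one analysis block's outcome-by-predictor effect-size matrix as a
#' heatmap, with cells below the corrected significance cut-off drawn white,
#' the standard masking convention for these matrices.
#'
#' @param run A `pheno_run` from [run_pipeline()].
#' @param block Block name to plot (default: first block).
#' @return A ggplot object.
#' @export
plot_effect_matrix <- function(run, block = names(run$matrices)[1]) {
  stopifnot(inherits(run, "pheno_run"), block %in% names(run$matrices))
  df <- run$effects |>
    dplyr::filter(.data$block == !!block) |>
    dplyr::mutate(es_masked = ifelse(.data$significant, .data$effect_size, NA))
  lim <- max(abs(df$effect_size), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$outcome,
                                   fill = .data$es_masked)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "white", high = "#B2182B",
      midpoint = 0, limits = c(-lim, lim), na.value = "white",
      name = "Effect size"
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = paste("Block:", block),
                  subtitle = paste0("white: p_adj >= ", run$report$alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname plot_effect_matrix
#' @param object A `pheno_run`.
#' @param ... Passed to [plot_effect_matrix()].
#' @exportS3Method ggplot2::autoplot
autoplot.pheno_run <- function(object, ...) plot_effect_matrix(object, ...)

#' Effect-size plot for a single model fit
#'
#' Dot-and-interval plot of per-predictor effect sizes (`t / sqrt(dfe)`) with
#' approximate 95% intervals (`es +/- 1.96 / sqrt(dfe)`).
#'
#' @param object A `pheno_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pheno_fit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(
      lo = .data$effect_size - 1.96 / sqrt(.data$dfe),
      hi = .data$effect_size + 1.96 / sqrt(.data$dfe)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect_size, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(
      x = "Effect size (t / sqrt(dfe))", y = NULL,
      title = if (!is.na(object$outcome)) object$outcome else NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
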