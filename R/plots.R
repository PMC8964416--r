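# ggplot2 figures for the main result types.

#' Plot a quantitative score against pathologist categories
#'
#' Dot/box plot of a per-core score grouped by the pathologist's three-level
#' category, the standard visual check of scorer concordance.
#'
#' @param core_scores Output of [score_cores()].
#' @param cores Core tibble with the pathologist category columns.
#' @param score `"immune_score"` or `"stroma_score"`.
#' @param category Category column, default matched to the score.
#' @return A ggplot object.
#' @export
plot_score_by_category <- function(core_scores, cores,
                                   score = c("immune_score", "stroma_score"),
                                   category = NULL) {
  score <- match.arg(score)
  category <- category %||%
    if (score == "immune_score") "path_immune" else "path_stroma"
  d <- dplyr::inner_join(core_scores, cores[, c("core_id", category)],
                         by = "core_id")
  d[[category]] <- factor(d[[category]], levels = c("low", "moderate", "high"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[category]], y = .data[[score]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "Pathologist category", y = score) +
    ggplot2::theme_bw()
}

#' Kaplan-Meier plot
#'
#' @param x A `km_result` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot object (step curves per group, log-rank p annotated).
#' @method autoplot km_result
#' @export
autoplot.km_result <- function(x, ...) {
  # prepend t = 0, S = 1 for each group
  d0 <- x$curves |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1, n_risk = NA_integer_)
  d <- dplyr::bind_rows(d0, x$curves)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability",
                  subtitle = sprintf("log-rank p = %.3g", x$logrank_p)) +
    ggplot2::theme_bw()
}

#' Forest plot of Cox hazard ratios
#'
#' @param forest Tibble with `quantity` (or `term`), `hr`, `ci_low`,
#'   `ci_high` — e.g. the `cox_univariate` element of a `tma_analysis`,
#'   filtered to one workflow/endpoint.
#' @return A ggplot object on a log HR axis.
#' @export
plot_forest <- function(forest) {
  lab <- if ("quantity" %in% names(forest)) "quantity" else "term"
  ggplot2::ggplot(forest, ggplot2::aes(x = .data$hr, y = .data[[lab]])) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_bw()
}

#' Heatmap of the subtype Spearman correlation matrix
#'
#' @param mat Correlation matrix from [spearman_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(mat) {
  d <- tibble::as_tibble(mat, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "rho")
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}
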