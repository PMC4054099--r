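#' Volcano plot of expressed-fraction comparisons
#'
#' Plots log2 ratio of expressed fractions (group vs rest) against
#' -log10 chi-squared p-value, one point per comparison (typically one per
#' context or gene group). Undefined comparisons are dropped.
#'
#' @param comparisons Tibble of rows from
#'   [expressed_fraction_comparison()], optionally with a `label` column.
#' @param p_cutoff Horizontal significance guide (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(comparisons, p_cutoff = 0.05) {
  df <- dplyr::filter(comparisons, !.data$undefined)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2ratio,
                                        y = -log10(.data$p_value))) +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted",
                        colour = "grey70") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "log2 ratio of expressed fractions (group / rest)",
                  y = expression(-log[10] ~ italic(P) ~ "(chi-squared)")) +
    ggplot2::theme_minimal()
  if ("label" %in% names(df)) {
    p <- p + ggplot2::aes(colour = .data$label)
  }
  p
}

#' Plot the coding-length vs recurrence trend
#'
#' @param object A `length_trend` from [length_recurrence_trend()].
#' @param ... Unused.
#' @return A ggplot object showing the fitted points and the OLS line.
#' @export
autoplot.length_trend <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$level,
                                            y = .data$length_bp)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "recurrence (number of cancer types or samples)",
                  y = "coding length (bp)",
                  subtitle = sprintf("slope = %.1f bp/unit, R² = %.3f",
                                     g$slope, g$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot where mutated genes fall out of the driver cascade
#'
#' Bar chart of first-failure stages across all traced (sample, gene)
#' pairs, with surviving driver calls shown as `driver`.
#'
#' @param object A `driver_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.driver_report <- function(object, ...) {
  df <- object$traces |>
    dplyr::mutate(stage = dplyr::coalesce(.data$failure_stage, "driver")) |>
    dplyr::count(.data$stage) |>
    dplyr::mutate(stage = factor(.data$stage,
                                 levels = c("unannotated", "expression",
                                            "damaging", "length", "systems",
                                            "driver")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "first failing stage (driver = all stages passed)",
                  y = "mutated (sample, gene) pairs") +
    ggplot2::theme_minimal()
}

#' Plot gene silencing effect distributions by group
#'
#' @param effects Tibble from [gene_effect()] with an added `group` column
#'   (e.g. tumour suppressor / known / non-mutated).
#' @return A ggplot box plot of `effect` by `group`.
#' @export
plot_silencing_groups <- function(effects) {
  stopifnot("group" %in% names(effects))
  ggplot2::ggplot(dplyr::filter(effects, !is.na(.data$effect)),
                  ggplot2::aes(x = .data$group, y = .data$effect)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(x = NULL,
                  y = expression(log[2] ~ "ratio (cell line / DNA pool)")) +
    ggplot2::theme_minimal()
}
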