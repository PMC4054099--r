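#' Consensus call of damaging mutations
#'
#' Truncating mutations (frameshift, nonsense, splice-site) are always
#' damaging. A missense mutation is damaging when at least two of three
#' predictors agree: damage-oriented SIFT score strictly above `sift_thr`,
#' PolyPhen score strictly above `polyphen_thr`, or a MutationTaster
#' `disease_causing` label. A missing score counts as a negative vote, so
#' the two-of-three denominator never shrinks. Synonymous and `other`
#' mutations are never damaging.
#'
#' @param mutations Mutation tibble (see [read_mutation_table()]).
#' @param sift_thr,polyphen_thr Predictor score thresholds in (0, 1);
#'   votes require strictly greater scores.
#' @return The input with columns `is_damaging` (logical), `basis`
#'   (`"truncating_class"`, `"missense_consensus"` or `"not_damaging"`)
#'   and `votes` (0-3 predictor votes) appended.
#' @export
damaging_call <- function(mutations, sift_thr = 0.95, polyphen_thr = 0.9) {
  stopifnot(sift_thr > 0, sift_thr < 1, polyphen_thr > 0, polyphen_thr < 1)
  truncating <- c("frameshift", "nonsense", "splice_site")
  v_sift <- !is.na(mutations$sift_damage_score) &
    mutations$sift_damage_score > sift_thr
  v_poly <- !is.na(mutations$polyphen_score) &
    mutations$polyphen_score > polyphen_thr
  v_mt <- !is.na(mutations$mutation_taster_call) &
    mutations$mutation_taster_call == "disease_causing"
  votes <- as.integer(v_sift) + as.integer(v_poly) + as.integer(v_mt)
  is_trunc <- mutations$mutation_class %in% truncating
  is_missense_hit <- mutations$mutation_class == "missense" & votes >= 2
  dplyr::mutate(mutations,
                votes = votes,
                is_damaging = is_trunc | is_missense_hit,
                basis = dplyr::case_when(
                  is_trunc ~ "truncating_class",
                  is_missense_hit ~ "missense_consensus",
                  TRUE ~ "not_damaging"))
}

#' Count mutation recurrence per gene
#'
#' Counts, for each mutated gene, the number of distinct cancer types and
#' distinct samples in which it carries at least one mutation. A gene
#' mutated twice in the same sample counts once for that sample.
#'
#' @param mutations Mutation tibble.
#' @param sample_to_cancer_type Named character vector mapping every
#'   `sample_id` to exactly one cancer type.
#' @return A tibble `(gene_id, n_cancer_types, n_samples)`.
#' @export
recurrence_counts <- function(mutations, sample_to_cancer_type) {
  unmapped <- setdiff(unique(mutations$sample_id),
                      names(sample_to_cancer_type))
  if (length(unmapped) > 0) {
    abort(sprintf("sample '%s' has no cancer-type mapping", unmapped[1]))
  }
  mutations |>
    dplyr::distinct(.data$gene_id, .data$sample_id) |>
    dplyr::mutate(cancer_type = unname(
      sample_to_cancer_type[.data$sample_id])) |>
    dplyr::summarise(n_cancer_types = dplyr::n_distinct(.data$cancer_type),
                     n_samples = dplyr::n_distinct(.data$sample_id),
                     .by = "gene_id")
}

#' Trend of coding length with mutation recurrence
#'
#' Longer genes accumulate more passenger mutations, so recurrently mutated
#' genes tend to be long. This fits an ordinary least-squares line of
#' coding length against recurrence level. By default the fit is on the
#' median coding length at each recurrence level (robust to the long length
#' tail); `fit_all_points = TRUE` fits every gene instead.
#'
#' @param genes Tibble with `coding_length_bp` and a recurrence column.
#' @param recurrence Name of the recurrence column (e.g. `n_cancer_types`
#'   or `n_samples`).
#' @param fit_all_points Fit gene-level points rather than per-level
#'   medians.
#' @return A `length_trend` object (a wrapper around the [stats::lm] fit)
#'   with `tidy()` and `glance()` methods; `glance()` reports `slope`
#'   (bp per recurrence unit), `r_squared` and `n_levels`.
#' @export
length_recurrence_trend <- function(genes, recurrence = "n_cancer_types",
                                    fit_all_points = FALSE) {
  if (!recurrence %in% names(genes)) {
    abort(sprintf("column '%s' not found", recurrence))
  }
  df <- tibble::tibble(level = genes[[recurrence]],
                       length_bp = genes$coding_length_bp)
  df <- df[!is.na(df$level) & !is.na(df$length_bp), ]
  n_levels <- dplyr::n_distinct(df$level)
  if (n_levels < 3) {
    abort("need at least 3 distinct recurrence levels to fit a trend")
  }
  fit_df <- if (fit_all_points) df else
    dplyr::summarise(df, length_bp = median(.data$length_bp), .by = "level")
  fit <- stats::lm(length_bp ~ level, data = fit_df)
  structure(list(fit = fit, n_levels = n_levels,
                 fit_all_points = fit_all_points, data = fit_df),
            class = "length_trend")
}

#' @export
print.length_trend <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<length_trend> slope = %.1f bp per recurrence unit, R^2 = %.3f (%d levels, %s fit)\n",
              g$slope, g$r_squared, g$n_levels,
              if (x$fit_all_points) "gene-level" else "per-level median"))
  invisible(x)
}

#' @rdname length_recurrence_trend
#' @param x A `length_trend` object.
#' @param ... Unused.
#' @export
tidy.length_trend <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @rdname length_recurrence_trend
#' @export
glance.length_trend <- function(x, ...) {
  tibble::tibble(slope = unname(stats::coef(x$fit)["level"]),
                 r_squared = summary(x$fit)$r.squared,
                 n_levels = x$n_levels)
}

#' Per-gene mutation summary table
#'
#' @param mutations Mutation tibble.
#' @param sample_to_cancer_type Named sample-to-type map.
#' @inheritParams damaging_call
#' @return Tibble `(gene_id, n_cancer_types, n_samples, n_damaging)`.
#' @export
mutation_summary <- function(mutations, sample_to_cancer_type,
                             sift_thr = 0.95, polyphen_thr = 0.9) {
  rec <- recurrence_counts(mutations, sample_to_cancer_type)
  dmg <- damaging_call(mutations, sift_thr, polyphen_thr) |>
    dplyr::summarise(n_damaging = sum(.data$is_damaging), .by = "gene_id")
  dplyr::left_join(rec, dmg, by = "gene_id")
}
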