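#' Construct an shRNA screen object
#'
#' A pooled shRNA dropout screen: hairpin abundances measured in the
#' replicates of each cell line and of the initial DNA pool (the reference
#' library representation). Each data column belongs to exactly one
#' replicate group.
#'
#' @param scores Numeric probe x condition matrix with probe row names and
#'   condition column names.
#' @param probe_map Tibble `(probe_id, gene_id)`; `gene_id` may be `NA`.
#' @param groups Tibble `(condition_id, group_id)` covering every column;
#'   when `NULL`, every column is its own group.
#' @param reference_group `group_id` of the initial DNA pool.
#' @param normalize `"none"` (pass input scores through, the default) or
#'   `"median"` (scale each condition so its median matches the grand
#'   median; requires positive medians).
#' @return An `shrna_screen` list.
#' @export
shrna_screen <- function(scores, probe_map, groups = NULL,
                         reference_group = "DNA", normalize = c("none",
                                                                "median")) {
  normalize <- match.arg(normalize)
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  if (is.null(groups)) {
    groups <- tibble::tibble(condition_id = colnames(scores),
                             group_id = colnames(scores))
  }
  missing_cond <- setdiff(colnames(scores), groups$condition_id)
  if (length(missing_cond) > 0) {
    abort(sprintf("condition '%s' has no replicate group", missing_cond[1]))
  }
  if (anyDuplicated(groups$condition_id)) {
    abort("each condition must belong to exactly one group")
  }
  if (normalize == "median") {
    med <- apply(scores, 2, median)
    if (any(med <= 0)) abort("median scaling needs positive column medians")
    scores <- sweep(scores, 2, med / stats::median(scores), "/")
    inform("shrna_screen: per-condition median scaling applied")
  }
  structure(list(scores = scores, probe_map = probe_map, groups = groups,
                 reference_group = reference_group,
                 normalize = normalize),
            class = "shrna_screen")
}

#' @export
print.shrna_screen <- function(x, ...) {
  cat(sprintf("<shrna_screen> %d probes x %d conditions in %d groups (reference: %s)\n",
              nrow(x$scores), ncol(x$scores),
              dplyr::n_distinct(x$groups$group_id), x$reference_group))
  invisible(x)
}

group_cols <- function(screen, group) {
  cols <- screen$groups$condition_id[screen$groups$group_id == group]
  cols <- intersect(colnames(screen$scores), cols)
  if (length(cols) == 0) abort(sprintf("no conditions in group '%s'", group))
  cols
}

#' Per-probe silencing log2 ratio
#'
#' For probe i and cell line h, the silencing effect is
#' `log2( mean_j score(h, i, j) / mean_k score(DNA, i, k) )` — the log2
#' ratio between the mean hairpin abundance over the cell-line replicates
#' and over the initial DNA-pool replicates. Positive values mean the
#' hairpin was enriched in the final cell population, i.e. silencing the
#' target increased proliferation. Ratios with a non-positive mean on
#' either side are undefined and returned as `NA`, never clamped.
#'
#' @param screen An [shrna_screen()].
#' @param cell_line Replicate-group id of the cell line.
#' @param probes Probe ids (default: all probes).
#' @return Named numeric vector of log2 ratios along `probes`.
#' @export
probe_log2ratio <- function(screen, cell_line, probes = NULL) {
  probes <- probes %||% rownames(screen$scores)
  absent <- setdiff(probes, rownames(screen$scores))
  if (length(absent) > 0) {
    abort(sprintf("probe '%s' absent from the screen", absent[1]))
  }
  hc <- group_cols(screen, cell_line)
  rc <- group_cols(screen, screen$reference_group)
  m_h <- rowMeans(screen$scores[probes, hc, drop = FALSE])
  m_r <- rowMeans(screen$scores[probes, rc, drop = FALSE])
  out <- rep(NA_real_, length(probes))
  ok <- m_h > 0 & m_r > 0
  out[ok] <- log2(m_h[ok] / m_r[ok])
  setNames(out, probes)
}

#' Gene-level silencing effect (top-probe collapse)
#'
#' Genes are typically targeted by several hairpins (a median of five in
#' large screens). The representative per-gene effect is the top-scoring
#' probe: the maximum log2 ratio with `direction = "max"` (proliferation
#' readout, the default), or the minimum with `"min"` for depletion
#' analyses. Probes with undefined ratios are ignored; a gene whose probes
#' are all undefined gets `NA`.
#'
#' @param screen An [shrna_screen()].
#' @param cell_lines Replicate-group ids (default: all non-reference
#'   groups).
#' @param direction `"max"` or `"min"`.
#' @return A tibble `(gene_id, cell_line, effect, n_probes)`, where
#'   `n_probes` counts probes with a defined ratio.
#' @export
gene_effect <- function(screen, cell_lines = NULL,
                        direction = c("max", "min")) {
  direction <- match.arg(direction)
  cell_lines <- cell_lines %||%
    setdiff(unique(screen$groups$group_id), screen$reference_group)
  collapse_fun <- if (direction == "max") max else min
  purrr::map_dfr(cell_lines, function(h) {
    lr <- probe_log2ratio(screen, h)
    tibble::tibble(probe_id = names(lr), ratio = unname(lr)) |>
      dplyr::inner_join(screen$probe_map, by = "probe_id") |>
      dplyr::filter(!is.na(.data$gene_id)) |>
      dplyr::summarise(
        effect = if (all(is.na(.data$ratio))) NA_real_ else
          collapse_fun(.data$ratio, na.rm = TRUE),
        n_probes = sum(!is.na(.data$ratio)),
        .by = "gene_id") |>
      dplyr::mutate(cell_line = h, .after = "gene_id")
  })
}

#' Count cell lines with increased proliferation upon silencing
#'
#' @param effects Tibble from [gene_effect()].
#' @param genes Gene ids to report (default: all in `effects`).
#' @param threshold Effect cutoff; a line counts when the gene effect is
#'   strictly above it (0 = any enrichment over the DNA pool).
#' @return A tibble `(gene_id, n_lines_increased, n_lines_tested,
#'   n_lines_missing)`.
#' @export
proliferation_count <- function(effects, genes = NULL, threshold = 0) {
  genes <- genes %||% unique(effects$gene_id)
  effects |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::summarise(
      n_lines_increased = sum(!is.na(.data$effect) &
                                .data$effect > threshold),
      n_lines_tested = sum(!is.na(.data$effect)),
      n_lines_missing = sum(is.na(.data$effect)),
      .by = "gene_id")
}

#' Compare silencing-effect distributions between two gene groups
#'
#' Two-sided Wilcoxon rank-sum test between the gene-level silencing
#' effects of two groups (for example tumour suppressors vs non-mutated
#' genes). Shapiro-Wilk p-values document the distribution shapes; the
#' Wilcoxon test is used regardless.
#'
#' @param effects_a,effects_b Numeric vectors of gene effects (length >=
#'   3 each; `NA` dropped first).
#' @return One-row tibble `(wilcoxon_p, shapiro_p_a, shapiro_p_b,
#'   median_a, median_b)`.
#' @export
compare_silencing_groups <- function(effects_a, effects_b) {
  compare_breadth_distributions(effects_a[!is.na(effects_a)],
                                effects_b[!is.na(effects_b)])
}
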