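#' Call gene expression from probe detection p-values
#'
#' A gene is called `expressed` in a context (tissue or tumour sample) when
#' at least half of its probes have a detection p-value strictly below
#' `alpha` (so with 3 probes, 2 are required). Contexts where a gene has no
#' probes yield `no_data`. When the probe table carries a `level` column,
#' the gene-level expression level is the mean of its probe levels.
#'
#' @param probes Probe detection tibble with columns `probe_id`, `gene_id`,
#'   `context_id`, `detection_p` and optionally `level`.
#' @param alpha Detection p-value cutoff, in (0, 1).
#' @param contexts,genes Optional vectors forcing the full context and gene
#'   universe; pairs without probes are emitted as `no_data`.
#' @return A tibble `(context_id, gene_id, call, level)` with `call` one of
#'   `"expressed"`, `"not_expressed"`, `"no_data"`. Every requested
#'   (context, gene) pair is present.
#' @export
call_expression <- function(probes, alpha = 0.05,
                            contexts = NULL, genes = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  if (!"level" %in% names(probes)) probes$level <- NA_real_
  contexts <- contexts %||% unique(probes$context_id)
  genes <- genes %||% unique(probes$gene_id)
  if (nrow(probes) == 0) {
    calls <- tibble::tibble(context_id = character(), gene_id = character(),
                            call = character(), level = double())
  } else {
    calls <- probes |>
      dplyr::summarise(
        call = ifelse(sum(.data$detection_p < alpha) * 2 >= dplyr::n(),
                      "expressed", "not_expressed"),
        level = mean(.data$level),
        .by = c("context_id", "gene_id"))
  }
  full <- tidyr::expand_grid(context_id = contexts, gene_id = genes)
  out <- dplyr::left_join(full, calls, by = c("context_id", "gene_id"))
  out$call[is.na(out$call)] <- "no_data"
  out$level[out$call == "no_data"] <- NA_real_
  out
}

#' Classify a gene's breadth of expression
#'
#' Breadth is the number of surveyed tissues in which a gene is called
#' expressed. Housekeeping genes are expressed in at least `hk_frac` of the
#' tissues (107 of 109 at the default 98%); tissue-selective genes in
#' strictly less than `ts_frac` (27 of 109 at the default 25%); the
#' remainder are intermediate.
#'
#' @param n_expressed Integer vector of tissues where the gene is expressed.
#' @param n_total Total number of surveyed tissues (scalar or vector).
#' @param hk_frac Housekeeping fraction cutoff (inclusive).
#' @param ts_frac Tissue-selective fraction cutoff (exclusive).
#' @return Character vector: `"housekeeping"`, `"tissue_selective"` or
#'   `"intermediate"`.
#' @export
classify_breadth <- function(n_expressed, n_total, hk_frac = 0.98,
                             ts_frac = 0.25) {
  stopifnot(ts_frac > 0, ts_frac < hk_frac, hk_frac <= 1)
  if (any(n_total == 0)) abort("n_total must be positive")
  if (any(n_expressed < 0 | n_expressed > n_total)) {
    abort("n_expressed must lie in [0, n_total]")
  }
  # 1e-9 guard: binary fractions like 0.98 * 100 land just above the integer
  hk_cut <- ceiling(hk_frac * n_total - 1e-9)     # expressed in >= hk_cut
  ts_cut <- ceiling(ts_frac * n_total - 1e-9) - 1 # largest int < ts_frac * n
  dplyr::case_when(
    n_expressed >= hk_cut ~ "housekeeping",
    n_expressed <= ts_cut ~ "tissue_selective",
    TRUE ~ "intermediate"
  )
}

#' Summarise breadth of expression per gene
#'
#' @param calls Expression call tibble from [call_expression()] over a
#'   tissue panel.
#' @inheritParams classify_breadth
#' @return A tibble `(gene_id, n_expressed, n_total, breadth_class)`.
#'   Contexts with `no_data` are excluded from both counts.
#' @export
breadth_summary <- function(calls, hk_frac = 0.98, ts_frac = 0.25) {
  calls |>
    dplyr::filter(.data$call != "no_data") |>
    dplyr::summarise(n_expressed = sum(.data$call == "expressed"),
                     n_total = dplyr::n(), .by = "gene_id") |>
    dplyr::mutate(breadth_class = classify_breadth(
      .data$n_expressed, .data$n_total, hk_frac, ts_frac))
}

# uncorrected 2x2 chi-squared: N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d));
# Yates subtracts N/2 from |ad - bc| (floored at 0) before squaring
chisq2x2 <- function(a, b, c, d, yates = FALSE) {
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(c(stat = NA_real_, p = NA_real_))
  stat <- n * num^2 / denom
  c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Compare expressed fractions between a gene group and the rest
#'
#' Computes the fraction of genes called expressed in a context within a
#' group of interest (for example, all mutated genes of one class) and
#' within a disjoint rest group, their log2 ratio, and the uncorrected
#' one-degree-of-freedom chi-squared test on the underlying 2x2 table —
#' the statistic behind each point of a volcano plot. In
#' `mode = "highly_expressed"` a gene counts as positive when its level
#' exceeds the context median level over all genes with data; genes with a
#' call but no level are excluded in that mode.
#'
#' Genes with `no_data` in the context are excluded from numerator and
#' denominator. The log2 ratio is `NA` (flagged `undefined = TRUE`)
#' whenever either fraction is zero; an empty group yields an undefined
#' comparison rather than an error.
#'
#' @param calls Expression call tibble from [call_expression()].
#' @param group_genes,rest_genes Disjoint character vectors of gene ids.
#' @param context Context (tissue or sample) identifier.
#' @param mode `"expressed"` or `"highly_expressed"`.
#' @param yates Apply the Yates continuity correction (off by default).
#' @return A one-row tibble: `context_id`, `mode`, `f_group`, `f_rest`,
#'   `log2ratio`, `chi2_stat`, `p_value`, `undefined`, and the 2x2 counts
#'   `n_group_pos`, `n_group_neg`, `n_rest_pos`, `n_rest_neg`.
#' @export
expressed_fraction_comparison <- function(calls, group_genes, rest_genes,
                                          context,
                                          mode = c("expressed",
                                                   "highly_expressed"),
                                          yates = FALSE) {
  mode <- match.arg(mode)
  if (length(intersect(group_genes, rest_genes)) > 0) {
    abort("group_genes and rest_genes must be disjoint")
  }
  ctx <- calls[calls$context_id == context & calls$call != "no_data", ]
  if (mode == "highly_expressed") {
    ctx <- ctx[!is.na(ctx$level), ]
    med <- median(ctx$level)
    ctx$positive <- ctx$level > med
  } else {
    ctx$positive <- ctx$call == "expressed"
  }
  g <- ctx[ctx$gene_id %in% group_genes, ]
  r <- ctx[ctx$gene_id %in% rest_genes, ]
  a <- sum(g$positive); b <- nrow(g) - a
  c_ <- sum(r$positive); d <- nrow(r) - c_
  f_g <- if (nrow(g) > 0) a / nrow(g) else NA_real_
  f_r <- if (nrow(r) > 0) c_ / nrow(r) else NA_real_
  undefined <- nrow(g) == 0 || nrow(r) == 0 || f_g == 0 || f_r == 0
  l2r <- if (!undefined) log2(f_g / f_r) else NA_real_
  chi <- if (nrow(g) > 0 && nrow(r) > 0) chisq2x2(a, b, c_, d, yates) else
    c(stat = NA_real_, p = NA_real_)
  tibble::tibble(context_id = context, mode = mode,
                 f_group = f_g, f_rest = f_r, log2ratio = l2r,
                 chi2_stat = unname(chi["stat"]),
                 p_value = unname(chi["p"]),
                 undefined = undefined,
                 n_group_pos = a, n_group_neg = b,
                 n_rest_pos = c_, n_rest_neg = d)
}

#' Test enrichment or depletion of a breadth class in a gene group
#'
#' Two-sided Fisher exact test on a 2x2 table of counts (for example,
#' housekeeping vs non-housekeeping by mutated vs non-mutated), as used for
#' small counts where the chi-squared approximation is unreliable. The
#' conditional maximum-likelihood odds ratio is reported, `NA` when a table
#' margin is zero.
#'
#' @param counts 2x2 integer matrix (or coercible).
#' @return A one-row tibble `(odds_ratio, p_value)`.
#' @export
class_enrichment_fisher <- function(counts) {
  m <- matrix(as.integer(counts), nrow = 2)
  if (any(m < 0)) abort("counts must be non-negative")
  if (sum(m) == 0) abort("all-zero table has no defined test")
  ft <- stats::fisher.test(m, alternative = "two.sided")
  or <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) NA_real_ else
    unname(ft$estimate)
  tibble::tibble(odds_ratio = or, p_value = ft$p.value)
}

#' Compare breadth (or any value) distributions between two gene groups
#'
#' Two-sided Wilcoxon rank-sum test between two groups of per-gene values
#' (typically breadth of expression). Shapiro-Wilk normality p-values are
#' reported for transparency only; they never switch the test.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 3.
#' @return A one-row tibble `(wilcoxon_p, shapiro_p_a, shapiro_p_b,
#'   median_a, median_b)`.
#' @export
compare_breadth_distributions <- function(group_a, group_b) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    abort("each group needs at least 3 values")
  }
  w <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                           alternative = "two.sided"))
  shp <- function(x) {
    if (length(unique(x)) < 3 || length(x) > 5000) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  tibble::tibble(wilcoxon_p = w$p.value,
                 shapiro_p_a = shp(group_a), shapiro_p_b = shp(group_b),
                 median_a = median(group_a), median_b = median(group_b))
}

#' Write an expression call matrix as a wide TSV
#'
#' @param calls Tibble from [call_expression()].
#' @param path Output path; one row per context, one column per gene.
#' @return `path`, invisibly.
#' @export
write_expression_calls <- function(calls, path) {
  wide <- calls |>
    dplyr::select("context_id", "gene_id", "call") |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "call")
  readr::write_tsv(wide, path)
  invisible(path)
}
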