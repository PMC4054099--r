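#' Pipeline configuration
#'
#' Collects every tunable threshold of the driver-prioritization cascade.
#' Defaults reproduce the published analysis settings: detection p < 0.05
#' for expression calls; SIFT > 0.95 / PolyPhen > 0.9 for the missense
#' consensus; the 4,450 bp coding-length cut (top 5% of human gene
#' lengths); long genes retained only when mutated in fewer than five
#' cancer types; hubs as the top 25% of degree and betweenness; and a
#' two-of-four systems-property requirement.
#'
#' @param alpha_detection Detection p-value cutoff for expression calls.
#' @param sift_thr,polyphen_thr Missense predictor thresholds.
#' @param length_thr_bp Coding-length cutoff in bp; genes strictly shorter
#'   bypass the recurrence check.
#' @param max_cancer_types_for_long Long genes are retained iff mutated in
#'   at most this many cancer types (4 = "fewer than five").
#' @param long_gene_rule `"methods"` (retain iff mutated in < 5 types, the
#'   default) or `"results"` (retain iff mutated in <= 5 types); the two
#'   published phrasings differ by one.
#' @param hub_quantile Quantile defining hub thresholds.
#' @param min_systems_true Minimum systems-level properties (0-4).
#' @param cancer_like_epochs Origin epochs counted as cancer-like.
#' @param require_known_expressed If `TRUE` (default) a sample is discarded
#'   only when a known cancer gene is both mutated and expressed in it; if
#'   `FALSE`, any known-gene mutation discards the sample.
#' @param exempt_known Known cancer genes exempted from the sample filter —
#'   used to re-admit samples mutated in a chosen tumour-suppressor set so
#'   the cascade can be benchmarked on recovering them.
#' @param seed Integer seed recorded with the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha_detection = 0.05,
                            sift_thr = 0.95,
                            polyphen_thr = 0.9,
                            length_thr_bp = 4450,
                            max_cancer_types_for_long = 4,
                            long_gene_rule = c("methods", "results"),
                            hub_quantile = 0.75,
                            min_systems_true = 2,
                            cancer_like_epochs = c("ancient", "metazoa",
                                                   "vertebrata"),
                            require_known_expressed = TRUE,
                            exempt_known = character(),
                            seed = 1L) {
  long_gene_rule <- match.arg(long_gene_rule)
  max_types <- if (long_gene_rule == "results") 5L else
    as.integer(max_cancer_types_for_long)
  stopifnot(alpha_detection > 0, alpha_detection < 1,
            length_thr_bp > 0, max_types >= 0,
            hub_quantile > 0, hub_quantile < 1,
            min_systems_true >= 0, min_systems_true <= 4)
  structure(list(alpha_detection = alpha_detection,
                 sift_thr = sift_thr, polyphen_thr = polyphen_thr,
                 length_thr_bp = length_thr_bp,
                 max_cancer_types_for_long = max_types,
                 long_gene_rule = long_gene_rule,
                 hub_quantile = hub_quantile,
                 min_systems_true = min_systems_true,
                 cancer_like_epochs = cancer_like_epochs,
                 require_known_expressed = require_known_expressed,
                 exempt_known = exempt_known,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [pipeline_config()] argument names exactly; absent keys
#' keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Sample-level filter of a cohort
#'
#' Discards (a) samples in which at least one known cancer gene outside
#' `exempt_known` is mutated — and, with `require_known_expressed`, also
#' called expressed in that sample (these tumours already carry a likely
#' driver); (b) samples whose mutated genes all lack expression data; and
#' (c) samples with no mutations at all.
#'
#' @param cohort A [cohort_bundle()].
#' @param config A [pipeline_config()].
#' @return A tibble `(sample_id, retained, reason)` with reason one of
#'   `"known_gene"`, `"no_expression_data"`, `"no_mutations"` or `NA` for
#'   retained samples.
#' @export
filter_samples <- function(cohort, config = pipeline_config()) {
  samples <- union(unique(cohort$mutations$sample_id),
                   names(cohort$sample_to_cancer_type))
  known <- setdiff(cohort$known_cancer_set, config$exempt_known)
  expr_key <- paste(cohort$expression$context_id, cohort$expression$gene_id,
                    sep = "\r")
  call_of <- function(sample_id, gene_id) {
    i <- match(paste(sample_id, gene_id, sep = "\r"), expr_key)
    ifelse(is.na(i), "no_data", cohort$expression$call[i])
  }
  per_sample <- function(s) {
    muts <- unique(cohort$mutations$gene_id[cohort$mutations$sample_id == s])
    if (length(muts) == 0) return("no_mutations")
    calls <- call_of(s, muts)
    known_hit <- muts %in% known &
      (if (config$require_known_expressed) calls == "expressed" else TRUE)
    if (any(known_hit)) return("known_gene")
    if (all(calls == "no_data")) return("no_expression_data")
    NA_character_
  }
  reason <- vapply(samples, per_sample, character(1))
  tibble::tibble(sample_id = samples, retained = is.na(reason),
                 reason = unname(reason))
}

#' Run the driver-prioritization cascade
#'
#' For every retained sample (see [filter_samples()]), each mutated gene is
#' pushed through four gene-level stages in order: (1) expressed in that
#' sample; (2) at least one damaging mutation in that sample
#' ([damaging_call()]); (3) short enough (coding length below
#' `length_thr_bp`) or, if long, mutated across few enough cancer types;
#' (4) at least `min_systems_true` of the four systems-level properties
#' ([systems_profile()]). Hub thresholds are computed once on the full
#' network. Genes lacking annotation fail with stage `unannotated`. The
#' run is deterministic for fixed inputs and configuration.
#'
#' @param cohort A [cohort_bundle()].
#' @param config A [pipeline_config()].
#' @return A `driver_report` with elements `drivers` (sample_id, gene_id),
#'   `traces` (full per-sample per-gene stage trace with `failure_stage`),
#'   `samples` (the [filter_samples()] table), `summary` (counts) and
#'   `config`. `tidy()` returns the traces, `glance()` the summary.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  samples <- filter_samples(cohort, config)
  cent <- compute_centralities(cohort$network)
  thr <- hub_thresholds(cent, config$hub_quantile)
  sysp <- systems_profile(cohort$genes, cohort$network, thr,
                          cohort$known_cancer_set,
                          config$cancer_like_epochs)

  dmg <- damaging_call(cohort$mutations, config$sift_thr,
                       config$polyphen_thr) |>
    dplyr::summarise(damaging = any(.data$is_damaging),
                     .by = c("sample_id", "gene_id"))

  traces <- cohort$mutations |>
    dplyr::distinct(.data$sample_id, .data$gene_id) |>
    dplyr::semi_join(dplyr::filter(samples, .data$retained),
                     by = "sample_id") |>
    dplyr::left_join(dplyr::select(cohort$expression, "context_id",
                                   "gene_id", "call"),
                     by = c(sample_id = "context_id", "gene_id")) |>
    dplyr::mutate(call = dplyr::coalesce(.data$call, "no_data")) |>
    dplyr::left_join(dmg, by = c("sample_id", "gene_id")) |>
    dplyr::left_join(dplyr::select(cohort$genes, "gene_id",
                                   "coding_length_bp",
                                   "n_cancer_types_mutated"),
                     by = "gene_id") |>
    dplyr::left_join(dplyr::select(sysp, "gene_id", "central_hub",
                                   "cancer_interactor", "cancer_like_origin",
                                   "singleton", "n_true"),
                     by = "gene_id") |>
    dplyr::mutate(
      annotated = !is.na(.data$coding_length_bp),
      expressed = .data$call == "expressed",
      length_ok = .data$annotated &
        (.data$coding_length_bp < config$length_thr_bp |
           dplyr::coalesce(.data$n_cancer_types_mutated, 0L) <=
             config$max_cancer_types_for_long),
      systems_ok = .data$annotated &
        passes_systems_filter(.data$n_true, config$min_systems_true),
      failure_stage = dplyr::case_when(
        !annotated ~ "unannotated",
        !expressed ~ "expression",
        !damaging ~ "damaging",
        !length_ok ~ "length",
        !systems_ok ~ "systems",
        TRUE ~ NA_character_),
      final_driver = is.na(.data$failure_stage)) |>
    dplyr::arrange(.data$sample_id, .data$gene_id)

  drivers <- traces |>
    dplyr::filter(.data$final_driver) |>
    dplyr::select("sample_id", "gene_id")

  summary <- tibble::tibble(
    n_samples_total = nrow(samples),
    n_samples_retained = sum(samples$retained),
    n_samples_discarded = sum(!samples$retained),
    n_samples_with_driver = dplyr::n_distinct(drivers$sample_id),
    n_driver_calls = nrow(drivers),
    n_driver_genes = dplyr::n_distinct(drivers$gene_id))

  structure(list(drivers = drivers, traces = traces, samples = samples,
                 hub_thresholds = thr, summary = summary, config = config),
            class = "driver_report")
}

#' @export
print.driver_report <- function(x, ...) {
  s <- x$summary
  cat("<driver_report>\n")
  cat(sprintf("  samples: %d total, %d retained, %d discarded\n",
              s$n_samples_total, s$n_samples_retained,
              s$n_samples_discarded))
  cat(sprintf("  drivers: %d calls of %d unique genes in %d samples\n",
              s$n_driver_calls, s$n_driver_genes, s$n_samples_with_driver))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `driver_report`.
#' @param ... Unused.
#' @export
tidy.driver_report <- function(x, ...) x$traces

#' @rdname run_pipeline
#' @export
glance.driver_report <- function(x, ...) x$summary

#' Recovery of planted (or known) drivers
#'
#' Scores a driver report against a truth map: a sample is a hit when at
#' least one of its true driver genes appears in its reported driver list;
#' sensitivity is the hit fraction over samples with truth.
#'
#' @param report A `driver_report`.
#' @param truth Tibble `(sample_id, gene_id)` of true drivers per sample.
#' @return A list with `per_sample` (sample_id, hit) and `sensitivity`.
#' @export
evaluate_recovery <- function(report, truth) {
  if (nrow(truth) == 0) abort("truth table is empty")
  per_sample <- truth |>
    dplyr::left_join(dplyr::mutate(report$drivers, reported = TRUE),
                     by = c("sample_id", "gene_id")) |>
    dplyr::summarise(hit = any(!is.na(.data$reported)), .by = "sample_id")
  list(per_sample = per_sample,
       sensitivity = mean(per_sample$hit))
}

#' Write all report tables of a pipeline run
#'
#' Writes `drivers.tsv`, `traces.tsv`, `discarded_samples.tsv` and
#' `summary.json` into a directory.
#'
#' @param report A `driver_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_driver_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$drivers, file.path(dir, "drivers.tsv"))
  readr::write_tsv(report$traces, file.path(dir, "traces.tsv"))
  readr::write_tsv(dplyr::filter(report$samples, !.data$retained),
                   file.path(dir, "discarded_samples.tsv"))
  jsonlite::write_json(as.list(report$summary),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
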