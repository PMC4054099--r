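#' Configuration of the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated tumour cohort with
#' known ground truth: coding lengths are log-normal with the top 5% near
#' the 4,450 bp cut; passenger mutations arrive per gene as a Poisson with
#' rate proportional to coding length; expression calls come from probe
#' detection p-values (expressed probes uniform on (0, alpha), silent
#' probes uniform on (alpha, 1)); the interaction network grows by
#' preferential attachment (heavy-tailed degrees); and the shRNA screen
#' draws positive hairpin abundances with planted suppressors shifted
#' upward in the cell-line replicates. A configured fraction of samples
#' carries a mutated and expressed known cancer gene (exercising the
#' sample filter); each remaining "clean" sample receives planted driver
#' genes that are, by construction, expressed, damagingly mutated, shorter
#' than `driver_length_max_bp` and carry at least two systems-level
#' properties (cancer-like origin and singleton status).
#'
#' @param n_samples,n_genes,n_tissues Cohort dimensions.
#' @param probe_weights Sampling weights for 1-5 probes per gene (default
#'   gives a median of five probes).
#' @param probe_coverage Fraction of genes with any probes; uncovered genes
#'   yield `no_data` calls.
#' @param fraction_known Fraction of genes in the known cancer set.
#' @param n_planted_drivers_per_clean_sample Planted drivers per clean
#'   sample.
#' @param fraction_samples_with_known_driver Fraction of samples given a
#'   mutated + expressed known cancer gene.
#' @param passenger_rate_per_bp Poisson passenger-mutation rate per coding
#'   bp per sample (0 gives a noise-free cohort).
#' @param length_meanlog,length_sdlog Log-normal coding-length parameters
#'   (bp).
#' @param driver_length_max_bp Maximum coding length of planted drivers.
#' @param driver_mutation_class `"frameshift"` (damaging by class) or
#'   `"missense"` (damaging via the two-of-three predictor consensus).
#' @param expression_rate Probability that a background gene is expressed
#'   in a given context.
#' @param alpha_detection Detection cutoff separating the two probe
#'   p-value regimes.
#' @param attachment Preferential-attachment edges added per node.
#' @param n_cancer_types Number of cancer types samples are spread over.
#' @param n_cell_lines,replicates_per_line,pool_replicates shRNA screen
#'   layout.
#' @param n_suppressors Planted suppressor genes in the screen.
#' @param suppressor_effect Mean log2 enrichment of suppressor hairpins in
#'   cell lines.
#' @param screen_noise_sd Per-replicate log2 noise of the screen.
#' @param seed Integer seed; the whole generation is deterministic in it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 100,
                             n_genes = 2000,
                             n_tissues = 109,
                             probe_weights = c(0.05, 0.1, 0.15, 0.2, 0.5),
                             probe_coverage = 0.9,
                             fraction_known = 0.02,
                             n_planted_drivers_per_clean_sample = 2,
                             fraction_samples_with_known_driver = 0.9,
                             passenger_rate_per_bp = 2e-5,
                             length_meanlog = log(1500),
                             length_sdlog = 0.67,
                             driver_length_max_bp = 4449,
                             driver_mutation_class = c("frameshift",
                                                       "missense"),
                             expression_rate = 0.5,
                             alpha_detection = 0.05,
                             attachment = 2,
                             n_cancer_types = 5,
                             n_cell_lines = 5,
                             replicates_per_line = 2,
                             pool_replicates = 2,
                             n_suppressors = 50,
                             suppressor_effect = 1,
                             screen_noise_sd = 0.3,
                             seed = 1L) {
  driver_mutation_class <- match.arg(driver_mutation_class)
  cfg <- as.list(environment())
  stopifnot(n_samples >= 1, n_genes >= 1, n_tissues >= 1,
            length(probe_weights) == 5, all(probe_weights >= 0),
            probe_coverage > 0, probe_coverage <= 1,
            fraction_known >= 0, fraction_known <= 1,
            n_planted_drivers_per_clean_sample >= 1,
            fraction_samples_with_known_driver >= 0,
            fraction_samples_with_known_driver <= 1,
            passenger_rate_per_bp >= 0,
            expression_rate >= 0, expression_rate <= 1,
            attachment >= 1, n_genes >= attachment + 1,
            n_cell_lines >= 1, replicates_per_line >= 1,
            pool_replicates >= 1, n_suppressors >= 0,
            screen_noise_sd >= 0)
  structure(cfg, class = "synthetic_config")
}

#' Scale-free interaction network by preferential attachment
#'
#' @param n_nodes Number of nodes.
#' @param attachment Edges added per incoming node (1 yields a tree).
#' @param seed Integer seed.
#' @param node_names Optional vertex names (default `N1..Nn`).
#' @return A connected undirected simple [igraph::graph].
#' @export
simulate_network <- function(n_nodes, attachment = 2, seed = 1L,
                             node_names = NULL) {
  if (n_nodes < attachment + 1) {
    abort("n_nodes must exceed the attachment parameter")
  }
  set.seed(as.integer(seed))
  g <- igraph::sample_pa(n_nodes, power = 1, m = attachment,
                         directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- node_names %||% paste0("N", seq_len(n_nodes))
  g
}

sample_origins <- function(n) {
  sample(origin_epochs, n, replace = TRUE,
         prob = c(0.3, 0.2, 0.2, 0.15, 0.1, 0.05))
}

passenger_classes <- c("missense", "synonymous", "nonsense", "frameshift",
                       "splice_site", "other")
passenger_class_probs <- c(0.62, 0.2, 0.05, 0.04, 0.03, 0.06)

driver_mutation_row <- function(sample_id, gene_id, class) {
  if (class == "frameshift") {
    tibble::tibble(sample_id = sample_id, gene_id = gene_id,
                   mutation_class = "frameshift",
                   sift_damage_score = NA_real_, polyphen_score = NA_real_,
                   mutation_taster_call = NA_character_,
                   conservation_score = stats::runif(length(gene_id),
                                                     0.95, 1))
  } else {
    tibble::tibble(sample_id = sample_id, gene_id = gene_id,
                   mutation_class = "missense",
                   sift_damage_score = stats::runif(length(gene_id),
                                                    0.96, 1),
                   polyphen_score = stats::runif(length(gene_id), 0.91, 1),
                   mutation_taster_call = "disease_causing",
                   conservation_score = stats::runif(length(gene_id),
                                                     0.95, 1))
  }
}

#' Generate a synthetic tumour cohort with known ground truth
#'
#' Produces a complete [cohort_bundle()] (gene annotation, mutations,
#' per-sample expression calls, interaction network, known cancer set,
#' sample-to-cancer-type map), a matching [shrna_screen()] with planted
#' suppressors, and the ground truth (planted drivers per clean sample and
#' suppressor flags). See [synthetic_config()] for the generative model.
#' Generation is fully deterministic in `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort` list with elements `bundle`, `screen`,
#'   `truth` (list of `drivers` tibble and `suppressors` character vector),
#'   `probes` (the probe detection table) and `config`.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  gid <- sprintf("G%04d", seq_len(config$n_genes))
  lengths <- pmax(150L, as.integer(round(stats::rlnorm(
    config$n_genes, config$length_meanlog, config$length_sdlog))))

  n_known <- round(config$fraction_known * config$n_genes)
  known <- sample(gid, n_known)
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  cancer_type <- setNames(
    paste0("type", (seq_along(samples) - 1) %% config$n_cancer_types + 1),
    samples)

  n_known_samples <- round(config$fraction_samples_with_known_driver *
                             config$n_samples)
  known_samples <- sort(sample(samples, n_known_samples))
  clean_samples <- setdiff(samples, known_samples)

  covered <- sample(gid, round(config$probe_coverage * config$n_genes))
  short <- gid[lengths <= config$driver_length_max_bp]
  eligible <- setdiff(intersect(covered, short), known)
  if (length(eligible) < config$n_planted_drivers_per_clean_sample) {
    abort("infeasible config: fewer eligible genes than planted drivers per sample")
  }
  if (n_known > 0 && length(intersect(known, covered)) == 0 &&
      length(known_samples) > 0) {
    abort("infeasible config: no known cancer gene is covered by probes")
  }
  known_covered <- intersect(known, covered)

  # plant drivers per clean sample
  planted <- purrr::map_dfr(clean_samples, function(s) {
    tibble::tibble(sample_id = s,
                   gene_id = sample(eligible,
                                    config$n_planted_drivers_per_clean_sample))
  })
  planted_genes <- unique(planted$gene_id)

  # annotation: planted drivers get cancer-like origin + singleton, so they
  # always carry >= 2 systems-level properties; everything else is random
  origin <- sample_origins(config$n_genes)
  dupl <- sample(c("singleton", "duplicated"), config$n_genes,
                 replace = TRUE, prob = c(0.4, 0.6))
  i_pl <- match(planted_genes, gid)
  origin[i_pl] <- sample(c("ancient", "metazoa", "vertebrata"),
                         length(i_pl), replace = TRUE)
  dupl[i_pl] <- "singleton"
  # pan-cancer recurrence reference grows with length (passenger load)
  n_types_ref <- pmin(20L, stats::rpois(config$n_genes,
                                        lambda = lengths / 2500))

  # mutations: one known-gene driver per known-driver sample, the planted
  # drivers of clean samples, plus length-proportional Poisson passengers
  mut_known <- if (length(known_samples) > 0) {
    driver_mutation_row(known_samples,
                        sample(known_covered, length(known_samples),
                               replace = TRUE),
                        config$driver_mutation_class)
  } else NULL
  mut_drivers <- if (nrow(planted) > 0) {
    driver_mutation_row(planted$sample_id, planted$gene_id,
                        config$driver_mutation_class)
  } else NULL
  mut_pass <- NULL
  if (config$passenger_rate_per_bp > 0) {
    lam <- config$passenger_rate_per_bp * lengths
    counts <- stats::rpois(config$n_samples * config$n_genes,
                           rep(lam, times = config$n_samples))
    hit <- which(counts > 0)
    if (length(hit) > 0) {
      n <- length(hit)
      mut_pass <- tibble::tibble(
        sample_id = samples[(hit - 1) %/% config$n_genes + 1],
        gene_id = gid[(hit - 1) %% config$n_genes + 1],
        mutation_class = sample(passenger_classes, n, replace = TRUE,
                                prob = passenger_class_probs),
        sift_damage_score = stats::runif(n),
        polyphen_score = stats::runif(n),
        mutation_taster_call = sample(c("disease_causing", "polymorphism"),
                                      n, replace = TRUE,
                                      prob = c(0.2, 0.8)),
        conservation_score = stats::runif(n))
    }
  }
  mutations <- dplyr::distinct(dplyr::bind_rows(mut_known, mut_drivers,
                                                mut_pass))

  gene_class <- rep("non_mutated", config$n_genes)
  gene_class[gid %in% unique(mutations$gene_id)] <- "other_mutated"
  gene_class[gid %in% known] <- "known"
  genes <- tibble::tibble(gene_id = gid, symbol = gid,
                          coding_length_bp = lengths,
                          gene_class = gene_class,
                          origin_epoch = origin, duplicability = dupl,
                          n_cancer_types_mutated = as.integer(n_types_ref))

  network <- simulate_network(config$n_genes, config$attachment,
                              seed = config$seed + 1L,
                              node_names = sample(gid))

  # expression: per (sample, gene) Bernoulli, forced TRUE for the planted
  # known gene / planted drivers of each sample; probe detection p-values
  # Uniform(0, alpha) for expressed genes and Uniform(alpha, 1) otherwise
  n_probes <- setNames(sample(1:5, config$n_genes, replace = TRUE,
                              prob = config$probe_weights), gid)
  forced <- dplyr::bind_rows(
    planted,
    if (!is.null(mut_known))
      dplyr::select(mut_known, "sample_id", "gene_id"))
  grid <- tidyr::expand_grid(context_id = samples, gene_id = covered)
  grid$expressed <- stats::runif(nrow(grid)) < config$expression_rate
  if (!is.null(forced) && nrow(forced) > 0) {
    fkey <- paste(forced$sample_id, forced$gene_id, sep = "\r")
    grid$expressed[paste(grid$context_id, grid$gene_id, sep = "\r") %in%
                     fkey] <- TRUE
  }
  np <- unname(n_probes[grid$gene_id])
  probes <- tibble::tibble(
    probe_id = paste0(rep(grid$gene_id, np), "_p",
                      sequence(np)),
    gene_id = rep(grid$gene_id, np),
    context_id = rep(grid$context_id, np),
    expressed = rep(grid$expressed, np))
  probes$detection_p <- ifelse(
    probes$expressed,
    stats::runif(nrow(probes), 0, config$alpha_detection),
    stats::runif(nrow(probes), config$alpha_detection, 1))
  probes$level <- stats::rnorm(nrow(probes),
                               mean = ifelse(probes$expressed, 8, 4), sd = 1)
  probes$expressed <- NULL
  expression <- call_expression(probes, alpha = config$alpha_detection,
                                contexts = samples, genes = gid)

  bundle <- suppressMessages(cohort_bundle(
    genes, mutations, expression, network,
    known_cancer_set = known,
    sample_to_cancer_type = cancer_type))

  screen <- simulate_screen(config, gid, n_probes)

  structure(list(bundle = bundle, screen = screen,
                 truth = list(drivers = planted,
                              suppressors = screen$suppressors),
                 probes = probes, config = config),
            class = "synthetic_cohort")
}

# shRNA screen: positive pool abundances, cell-line replicates multiplied by
# 2^(effect + noise); planted suppressors get effect = suppressor_effect
simulate_screen <- function(config, gid, n_probes) {
  suppressors <- sample(gid, min(config$n_suppressors, length(gid)))
  probe_gene <- rep(gid, unname(n_probes[gid]))
  probe_id <- paste0(probe_gene, "_sh", sequence(unname(n_probes[gid])))
  lines <- paste0("LINE", seq_len(config$n_cell_lines))
  conds <- c(paste0(rep(lines, each = config$replicates_per_line), "_r",
                    sequence(rep(config$replicates_per_line,
                                 config$n_cell_lines))),
             paste0("DNA_r", seq_len(config$pool_replicates)))
  groups <- tibble::tibble(
    condition_id = conds,
    group_id = c(rep(lines, each = config$replicates_per_line),
                 rep("DNA", config$pool_replicates)))
  base <- stats::rlnorm(length(probe_id), meanlog = 6, sdlog = 0.5)
  effect <- ifelse(probe_gene %in% suppressors, config$suppressor_effect, 0)
  scores <- matrix(NA_real_, length(probe_id), length(conds),
                   dimnames = list(probe_id, conds))
  for (j in seq_along(conds)) {
    shift <- if (groups$group_id[j] == "DNA") 0 else effect
    scores[, j] <- base * 2^(shift + stats::rnorm(length(probe_id), 0,
                                                  config$screen_noise_sd))
  }
  scr <- shrna_screen(scores,
                      tibble::tibble(probe_id = probe_id,
                                     gene_id = probe_gene),
                      groups = groups, reference_group = "DNA")
  scr$suppressors <- suppressors
  scr
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> seed %d\n", x$config$seed))
  print(x$bundle)
  cat(sprintf("  truth: %d planted driver calls in %d clean samples; %d screen suppressors\n",
              nrow(x$truth$drivers),
              dplyr::n_distinct(x$truth$drivers$sample_id),
              length(x$truth$suppressors)))
  invisible(x)
}

#' Simulate a normal-tissue expression panel
#'
#' Generates a probe detection table over `n_tissues` healthy-tissue
#' contexts for breadth-of-expression analyses. Each gene draws a breadth
#' fraction from a U-shaped Beta(0.4, 0.4) (many near-housekeeping and many
#' tissue-selective genes, as in real panels) and is expressed in that
#' fraction of tissues.
#'
#' @param config A [synthetic_config()]; uses `n_tissues`, `n_genes`,
#'   probe settings, `alpha_detection` and `seed`.
#' @return A probe detection tibble usable with [call_expression()].
#' @export
simulate_tissue_panel <- function(config = synthetic_config()) {
  set.seed(config$seed + 2L)
  gid <- sprintf("G%04d", seq_len(config$n_genes))
  tissues <- sprintf("T%03d", seq_len(config$n_tissues))
  breadth <- stats::rbeta(config$n_genes, 0.4, 0.4)
  n_probes <- sample(1:5, config$n_genes, replace = TRUE,
                     prob = config$probe_weights)
  grid <- tidyr::expand_grid(gene_id = gid, context_id = tissues)
  grid$expressed <- stats::runif(nrow(grid)) <
    rep(breadth, each = config$n_tissues)
  np <- rep(n_probes, each = config$n_tissues)
  probes <- tibble::tibble(
    probe_id = paste0(rep(grid$gene_id, np), "_p", sequence(np)),
    gene_id = rep(grid$gene_id, np),
    context_id = rep(grid$context_id, np),
    expressed = rep(grid$expressed, np))
  probes$detection_p <- ifelse(
    probes$expressed,
    stats::runif(nrow(probes), 0, config$alpha_detection),
    stats::runif(nrow(probes), config$alpha_detection, 1))
  probes$level <- stats::rnorm(nrow(probes),
                               mean = ifelse(probes$expressed, 8, 4), sd = 1)
  probes$expressed <- NULL
  probes
}

#' Write every input file of a synthetic cohort
#'
#' Writes the gene table, mutation table (simple dialect), probe detection
#' table, network edge list, GCT screen, replicate-group map,
#' sample-to-cancer-type map and `truth.tsv` into a directory, so the
#' cohort can be re-read through the package's own readers (or the CLI).
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- cohort$bundle
  readr::write_tsv(b$genes, file.path(dir, "genes.tsv"))
  write_mutation_table(b$mutations, file.path(dir, "mutations.tsv"))
  readr::write_tsv(cohort$probes, file.path(dir, "probes.tsv"))
  write_network(b$network, file.path(dir, "network.tsv"))
  write_gct(cohort$screen, file.path(dir, "screen.gct"))
  readr::write_tsv(cohort$screen$groups, file.path(dir, "screen_groups.tsv"))
  readr::write_tsv(tibble::tibble(sample_id = names(b$sample_to_cancer_type),
                                  cancer_type = unname(
                                    b$sample_to_cancer_type)),
                   file.path(dir, "samples.tsv"))
  readr::write_tsv(tibble::tibble(gene_id = b$known_cancer_set),
                   file.path(dir, "known_genes.tsv"))
  readr::write_tsv(cohort$truth$drivers, file.path(dir, "truth.tsv"))
  invisible(dir)
}
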