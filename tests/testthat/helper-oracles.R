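# Independent oracles, kept deliberately naive: they re-derive expected
# values by enumeration rather than by the code paths they check.

# Brute-force betweenness: enumerate every simple path between each node
# pair by depth-first search, keep the shortest ones, and count the
# fraction passing through each interior node. Feasible for <= 8 nodes.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  betw <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, visited) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- visited
        return()
      }
      for (w in which(adj[v, ] == 1)) {
        if (!w %in% visited) walk(w, c(visited, w))
      }
    }
    walk(s, s)
    paths
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, 1L)
      shortest <- paths[lens == min(lens)]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p, TRUE))
        betw[v] <- betw[v] + through / length(shortest)
      }
    }
  }
  betw
}

random_small_graph <- function(n, p = 0.45) {
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

adj_to_graph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(nrow(adj)))
  g
}

# Two-sided Fisher p by explicit hypergeometric enumeration over all
# tables with the observed margins.
enum_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(a_vals, function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1), 1.0)
  p_obs <- probs[a_vals == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small hand-traceable cohort: two samples, one discarded by the known-gene
# rule, one retained with exactly one gene passing every stage
toy_cohort <- function() {
  genes <- tibble::tibble(
    gene_id = c("KNOWN1", "DRV1", "LONGG", "SILENT", "BENIGN"),
    symbol = gene_id,
    coding_length_bp = c(2000L, 1200L, 6000L, 900L, 1500L),
    gene_class = c("known", "other_mutated", "other_mutated",
                   "other_mutated", "other_mutated"),
    origin_epoch = c("ancient", "metazoa", "ancient", "recent", "mammalia"),
    duplicability = c("singleton", "singleton", "singleton", "duplicated",
                      "duplicated"),
    n_cancer_types_mutated = c(3L, 1L, 7L, 1L, 1L))
  mutations <- tibble::tibble(
    sample_id = c("s1", "s2", "s2", "s2", "s2"),
    gene_id = c("KNOWN1", "DRV1", "LONGG", "SILENT", "BENIGN"),
    mutation_class = c("missense", "frameshift", "frameshift", "frameshift",
                       "missense"),
    sift_damage_score = c(0.99, NA, NA, NA, 0.2),
    polyphen_score = c(0.95, NA, NA, NA, 0.1),
    mutation_taster_call = c("disease_causing", NA, NA, NA, "polymorphism"),
    conservation_score = NA_real_)
  expression <- tidyr::expand_grid(context_id = c("s1", "s2"),
                                   gene_id = genes$gene_id) |>
    dplyr::mutate(call = dplyr::case_when(
      gene_id == "SILENT" ~ "not_expressed",
      TRUE ~ "expressed"),
      level = ifelse(call == "expressed", 8, 2))
  network <- igraph::make_graph(~ KNOWN1 - DRV1, DRV1 - LONGG,
                                LONGG - BENIGN)
  suppressMessages(cohort_bundle(
    genes, mutations, expression, network,
    sample_to_cancer_type = c(s1 = "ovarian", s2 = "ovarian")))
}

small_cohort <- function(seed, n_samples = 20, n_genes = 200, ...) {
  suppressWarnings(suppressMessages(simulate_cohort(
    synthetic_config(n_samples = n_samples, n_genes = n_genes, seed = seed,
                     ...))))
}

quiet_pipeline <- function(bundle, config = pipeline_config()) {
  suppressWarnings(suppressMessages(run_pipeline(bundle, config)))
}
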