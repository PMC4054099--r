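#' Degree and betweenness centrality of every network node
#'
#' Degree is the incident-edge count. Betweenness is the classical
#' unnormalized measure on the undirected graph: for node v, the sum over
#' unordered node pairs (s, t) with s != v != t of the fraction of shortest
#' s-t paths passing through v; disconnected pairs contribute zero and
#' endpoints are excluded. On a 13,531-protein interaction network the
#' upper-quartile values of these measures define central hubs.
#'
#' @param network Undirected simple [igraph::graph].
#' @return A tibble `(gene_id, degree, betweenness)`, one row per node.
#' @export
compute_centralities <- function(network) {
  if (igraph::vcount(network) == 0) abort("network has no nodes")
  tibble::tibble(
    gene_id = igraph::V(network)$name,
    degree = as.integer(igraph::degree(network)),
    betweenness = unname(igraph::betweenness(network, directed = FALSE,
                                             normalized = FALSE)))
}

#' Empirical hub thresholds for degree and betweenness
#'
#' Central hubs are the nodes in the top (1 - quantile) of both degree and
#' betweenness over all network nodes (the top 25% by default). Thresholds
#' are the empirical quantiles with the linear-interpolation convention
#' (R's default type 7), so they are bit-reproducible; a node is a hub only
#' if it strictly exceeds both.
#'
#' @param centralities Tibble from [compute_centralities()].
#' @param quantile Quantile in (0, 1) defining the cutoffs (0.75 keeps the
#'   top 25%).
#' @return A one-row tibble `(degree_thr, betweenness_thr, quantile)`.
#' @export
hub_thresholds <- function(centralities, quantile = 0.75) {
  if (nrow(centralities) == 0) abort("empty centrality table")
  if (quantile <= 0 || quantile >= 1) abort("quantile must be in (0, 1)")
  tibble::tibble(
    degree_thr = unname(stats::quantile(centralities$degree, quantile,
                                        type = 7)),
    betweenness_thr = unname(stats::quantile(centralities$betweenness,
                                             quantile, type = 7)),
    quantile = quantile)
}

#' Is a node a central hub?
#'
#' @param degree,betweenness Numeric vectors of node centralities.
#' @param thresholds One-row tibble from [hub_thresholds()].
#' @return Logical vector: strictly above both thresholds.
#' @export
is_central_hub <- function(degree, betweenness, thresholds) {
  degree > thresholds$degree_thr & betweenness > thresholds$betweenness_thr
}

#' Does a gene directly interact with a known cancer protein?
#'
#' True when at least one network neighbour of the gene belongs to the
#' known cancer gene set; the gene's own membership is ignored. Genes
#' absent from the network return `FALSE` with a warning — absence of
#' interaction evidence, not an error, since interaction networks cover
#' only part of the genome.
#'
#' @param network Undirected [igraph::graph].
#' @param genes Character vector of gene ids to query.
#' @param known_set Character vector of known cancer gene ids.
#' @return Logical vector along `genes`.
#' @export
cancer_interactor <- function(network, genes, known_set) {
  vs <- igraph::V(network)$name
  missing <- setdiff(unique(genes), vs)
  if (length(missing) > 0) {
    warn(sprintf("cancer_interactor: %d gene(s) absent from the network treated as non-interactors",
                 length(missing)))
  }
  known_nodes <- intersect(known_set, vs)
  # one adjacency pass: nodes adjacent to any known cancer protein
  touched <- if (length(known_nodes) == 0) character() else
    unique(unlist(lapply(igraph::adjacent_vertices(network, known_nodes),
                         function(v) v$name)))
  genes %in% touched
}

#' Systems-level profile of candidate genes
#'
#' Evaluates the four systems-level properties in which known cancer genes
#' are enriched: (1) central-hub status (top quantile of both degree and
#' betweenness); (2) direct interaction with a known cancer protein;
#' (3) cancer-like evolutionary origin — genes that arose early in
#' evolution or with metazoans/vertebrates; (4) singleton status (no human
#' paralog). Missing annotation or network absence makes the corresponding
#' flag `FALSE`.
#'
#' @param genes Gene tibble with `gene_id`, `origin_epoch`, `duplicability`.
#' @param network Undirected [igraph::graph].
#' @param thresholds One-row tibble from [hub_thresholds()].
#' @param known_set Known cancer gene ids.
#' @param cancer_like_epochs Origin epochs counted as cancer-like.
#' @return A tibble `(gene_id, degree, betweenness, central_hub,
#'   cancer_interactor, cancer_like_origin, singleton, n_true)`.
#' @export
systems_profile <- function(genes, network, thresholds, known_set,
                            cancer_like_epochs = c("ancient", "metazoa",
                                                   "vertebrata")) {
  cent <- compute_centralities(network)
  idx <- match(genes$gene_id, cent$gene_id)
  degree <- ifelse(is.na(idx), 0L, cent$degree[idx])
  betw <- ifelse(is.na(idx), 0, cent$betweenness[idx])
  hub <- !is.na(idx) & is_central_hub(degree, betw, thresholds)
  inter <- rep(FALSE, nrow(genes))
  in_net <- !is.na(idx)
  if (any(in_net)) {
    inter[in_net] <- cancer_interactor(network, genes$gene_id[in_net],
                                       known_set)
  }
  origin_ok <- !is.na(genes$origin_epoch) &
    genes$origin_epoch %in% cancer_like_epochs
  singleton <- !is.na(genes$duplicability) &
    genes$duplicability == "singleton"
  tibble::tibble(
    gene_id = genes$gene_id,
    degree = as.integer(degree), betweenness = betw,
    central_hub = hub, cancer_interactor = inter,
    cancer_like_origin = origin_ok, singleton = singleton,
    n_true = as.integer(hub) + as.integer(inter) + as.integer(origin_ok) +
      as.integer(singleton))
}

#' Final systems-level filter decision
#'
#' A gene passes when it shows at least `min_true` of the four
#' systems-level properties. The combination rule is deliberately a
#' parameter: requiring all four would be far stricter than the behaviour
#' of known cancer genes, while any-one-of-four is too permissive;
#' two-of-four is the default.
#'
#' @param n_true Integer vector of property counts (0-4).
#' @param min_true Minimum number of properties required (0 disables the
#'   filter).
#' @return Logical vector.
#' @export
passes_systems_filter <- function(n_true, min_true = 2) {
  stopifnot(min_true >= 0, min_true <= 4)
  n_true >= min_true
}
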