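#' Per-guild degree statistics
#'
#' Mean "connections per node" with its standard error, per guild. By
#' default only nodes that take part in at least one interaction are
#' counted (the nodes that appear in a drawn network); set
#' `include_isolated = TRUE` to average over the whole screened universe.
#'
#' @param network an `interaction_network`.
#' @param guild `"predator"`, `"prey"` or `"all"`.
#' @param include_isolated include screened nodes of degree 0.
#' @return one-row tibble with `guild`, `n_nodes`, `degree_mean`,
#'   `degree_se`.
#' @export
degree_stats <- function(network, guild = c("predator", "prey", "all"),
                         include_isolated = FALSE) {
  guild <- match.arg(guild)
  deg <- node_degrees(network, include_isolated = include_isolated)
  if (guild != "all") deg <- filter(deg, .data$guild == !!guild)
  if (nrow(deg) == 0) abort(paste0("no ", guild, " nodes in the network"))
  tibble(
    guild = guild,
    n_nodes = nrow(deg),
    degree_mean = mean(deg$degree),
    degree_se = if (nrow(deg) > 1) sd(deg$degree) / sqrt(nrow(deg)) else 0
  )
}

#' Per-node degrees
#' @inheritParams degree_stats
#' @return tibble with `otu_id`, `guild`, `degree`.
#' @export
node_degrees <- function(network, include_isolated = FALSE) {
  g <- as_igraph(network, include_isolated = include_isolated)
  tibble(otu_id = igraph::V(g)$name, guild = igraph::V(g)$guild,
         degree = igraph::degree(g))
}

#' Detect network communities (Louvain)
#'
#' Greedy Louvain modularity maximization on the undirected bipartite graph,
#' at resolution 1. The sweep is randomized, so it is restarted `restarts`
#' times from seeds derived from `seed` and the highest-modularity partition
#' is kept; the whole procedure is deterministic given `seed`. Nodes enter
#' the algorithm in sorted name order. Graphs with at most `exact_max`
#' nodes are instead solved to the exact modularity optimum
#' ([igraph::cluster_optimal()]).
#'
#' @param network an `interaction_network`.
#' @param seed base RNG seed for the restarted sweeps.
#' @param restarts number of independent Louvain sweeps.
#' @param exact_max largest node count for which the exact optimum is
#'   computed instead of the greedy search.
#' @return tibble `otu_id`, `guild`, `community` (integer ids), with the
#'   achieved modularity as attribute `"modularity"`.
#' @export
detect_communities <- function(network, seed = 1, restarts = 10, exact_max = 12) {
  if (nrow(network$edges) == 0) abort("cannot detect communities in an empty network")
  g <- as_igraph(network)
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  if (igraph::vcount(g) <= exact_max) {
    best <- igraph::cluster_optimal(g)
  } else {
    best <- NULL
    best_q <- -Inf
    for (k in seq_len(restarts)) {
      cl <- with_seed(seed + k - 1, igraph::cluster_louvain(g, resolution = 1))
      q <- igraph::modularity(g, igraph::membership(cl))
      if (q > best_q + 1e-12) {
        best <- cl
        best_q <- q
      }
    }
  }
  out <- tibble(otu_id = igraph::V(g)$name, guild = igraph::V(g)$guild,
                community = as.integer(igraph::membership(best)))
  attr(out, "modularity") <- modularity_q(network, setNames(out$community, out$otu_id))
  out
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum_c (e_c / m - (d_c / 2m)^2) over communities c, on the undirected
#' bipartite graph: within-community edge fraction minus its random
#' expectation under the degree-preserving null.
#'
#' @param network an `interaction_network`, or any undirected igraph graph.
#' @param partition named vector (node -> community) covering all network
#'   nodes, a tibble from [detect_communities()], or an unnamed vector in
#'   vertex order; `NULL` runs [detect_communities()] first (interaction
#'   networks only).
#' @param seed passed to [detect_communities()] when `partition` is `NULL`.
#' @return modularity Q (a number <= 1).
#' @export
modularity_q <- function(network, partition = NULL, seed = 1) {
  if (igraph::is_igraph(network)) {
    g <- network
    if (igraph::ecount(g) == 0) abort("modularity undefined for an edgeless graph")
    if (is.null(partition)) abort("a partition is required for a plain graph")
  } else {
    if (nrow(network$edges) == 0) abort("modularity undefined for an edgeless network")
    if (is.null(partition)) {
      part <- detect_communities(network, seed = seed)
      return(attr(part, "modularity"))
    }
    g <- as_igraph(network)
  }
  if (is.data.frame(partition)) {
    partition <- setNames(partition$community, partition$otu_id)
  }
  if (!is.null(names(partition))) {
    ids <- igraph::V(g)$name
    if (!all(ids %in% names(partition))) abort("partition must cover all network nodes")
    partition <- partition[ids]
  } else if (length(partition) != igraph::vcount(g)) {
    abort("unnamed partition must have one entry per vertex")
  }
  igraph::modularity(g, membership = as.integer(factor(partition)))
}

#' Shortest-path metrics and clustering coefficient
#'
#' Average path length and diameter are computed over reachable pairs only
#' (inferred networks are typically disconnected). The global clustering
#' coefficient (3 x triangles / connected triples) is structurally 0 for a
#' bipartite graph — a built-in sanity check on the network's bipartiteness.
#'
#' @param network an `interaction_network`.
#' @return one-row tibble: `average_path_length`, `diameter`,
#'   `clustering_coefficient`.
#' @export
path_metrics <- function(network) {
  if (nrow(network$edges) == 0) {
    return(tibble(average_path_length = NA_real_, diameter = NA_real_,
                  clustering_coefficient = 0))
  }
  g <- as_igraph(network)
  cc <- igraph::transitivity(g, type = "global")
  tibble(
    average_path_length = igraph::mean_distance(g, unconnected = TRUE),
    diameter = igraph::diameter(g, unconnected = TRUE),
    clustering_coefficient = if (is.nan(cc)) 0 else cc
  )
}

#' Cumulative degree distribution
#'
#' P(k) = fraction of nodes with degree >= k, for k = 0..max degree; always
#' starts at 1 and is non-increasing.
#'
#' @param network an `interaction_network`.
#' @param include_isolated include screened degree-0 nodes.
#' @return tibble with `degree`, `p_geq`.
#' @export
cumulative_degree_distribution <- function(network, include_isolated = FALSE) {
  deg <- node_degrees(network, include_isolated = include_isolated)$degree
  ks <- 0:max(c(deg, 0))
  tibble(degree = ks,
         p_geq = vapply(ks, function(k) mean(deg >= k), numeric(1)))
}

#' Full topology description of a network
#'
#' Bundles per-guild degree statistics, Louvain communities and modularity,
#' path metrics and the cumulative degree distribution.
#'
#' @param network an `interaction_network`.
#' @param seed seed for community detection.
#' @return a `network_topology` object (list), with [tidy()] (per-node
#'   degrees + community) and [glance()] (one-row summary) methods.
#' @export
network_topology <- function(network, seed = 1) {
  part <- detect_communities(network, seed = seed)
  structure(list(
    degrees = node_degrees(network),
    degree_stats = bind_rows(degree_stats(network, "predator"),
                             degree_stats(network, "prey")),
    partition = part,
    modularity_q = attr(part, "modularity"),
    path_metrics = path_metrics(network),
    cumulative_degree_distribution = cumulative_degree_distribution(network)
  ), class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat("Network topology\n")
  cat("  modularity Q:", format(x$modularity_q, digits = 3),
      "over", max(x$partition$community), "communities\n")
  print(x$degree_stats)
  print(x$path_metrics)
  invisible(x)
}

#' @describeIn network_topology per-node degrees and community memberships.
#' @param x a `network_topology`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.network_topology <- function(x, ...) {
  left_join(x$degrees, select(x$partition, "otu_id", "community"), by = "otu_id")
}

#' @describeIn network_topology one-row summary of the topology.
#' @exportS3Method generics::glance
glance.network_topology <- function(x, ...) {
  stats_wide <- tidyr::pivot_wider(
    x$degree_stats, names_from = "guild",
    values_from = c("n_nodes", "degree_mean", "degree_se"))
  dplyr::bind_cols(
    stats_wide,
    tibble(modularity_q = x$modularity_q,
           n_communities = max(x$partition$community)),
    x$path_metrics
  )
}
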