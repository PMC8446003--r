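#' Infer a bipartite predator-prey interaction network
#'
#' Runs the exhaustive negative-correlation screen: every predator series is
#' Kendall-correlated against every prey series over the shared, time-ordered
#' samples, and an edge (predator, prey) is retained iff tau < `tau_max` and
#' p < `alpha`. Under obligate predation, sustained predation depresses prey
#' abundance while predators track prey availability, so strong negative
#' rank correlation over a yearly series flags a potential trophic link.
#' The hard tau gate (default -0.7) is the principal sieve; no
#' multiple-testing correction is applied by default, matching the screening
#' design, but Benjamini-Hochberg adjustment is available.
#'
#' @param predators,prey `otu_tbl`s in relative mode over the same samples
#'   (typically one site-fraction series each); prey should already be
#'   filtered with [filter_min_reads()] and [filter_gram_positive()].
#' @param tau_max edge gate on Kendall tau (edge iff tau < `tau_max`).
#' @param alpha edge gate on the p-value (edge iff p < `alpha`).
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment across all defined pairs before gating.
#' @return an `interaction_network`: edge tibble (`predator_otu`,
#'   `prey_otu`, `tau`, `p_value`) plus the screened node universes and
#'   provenance (site, fraction, gates, n samples).
#' @export
infer_network <- function(predators, prey, tau_max = -0.7, alpha = 0.01,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stop_if_not_otu(predators)
  stop_if_not_otu(prey)
  if (table_mode(predators) != "relative" || table_mode(prey) != "relative") {
    abort("both tables must be in relative mode (see `relativize()`)")
  }
  mp <- sample_info(predators)
  my <- sample_info(prey)
  if (!identical(mp$sample_id, my$sample_id)) {
    abort("predator and prey tables must cover the same samples")
  }
  if (nrow(mp) < 5) abort("fewer than 5 shared time points: too little power to screen")
  X <- otu_matrix(predators)
  Y <- otu_matrix(prey)
  scr <- kendall_screen(X, Y)
  p <- scr$p
  if (p_adjust == "BH") {
    ok <- !is.na(p)
    p[ok] <- stats::p.adjust(p[ok], method = "BH")
  }
  hit <- which(!is.na(scr$tau) & scr$tau < tau_max & p < alpha, arr.ind = TRUE)
  edges <- tibble(
    predator_otu = colnames(X)[hit[, 1]],
    prey_otu = colnames(Y)[hit[, 2]],
    tau = scr$tau[hit],
    p_value = p[hit]
  ) %>% arrange(.data$predator_otu, .data$prey_otu)
  new_interaction_network(
    edges,
    predator_nodes = colnames(X),
    prey_nodes = colnames(Y),
    provenance = list(
      site = unique(mp$site), fraction = unique(mp$fraction),
      tau_max = tau_max, alpha = alpha, p_adjust = p_adjust, n_samples = nrow(mp)
    )
  )
}

new_interaction_network <- function(edges, predator_nodes, prey_nodes, provenance = list()) {
  if (anyDuplicated(edges[, c("predator_otu", "prey_otu")])) {
    abort("duplicate (predator, prey) edge")
  }
  if (!all(edges$predator_otu %in% predator_nodes) ||
      !all(edges$prey_otu %in% prey_nodes)) {
    abort("edge endpoints must come from the declared node universes")
  }
  if (length(intersect(predator_nodes, prey_nodes)) > 0) {
    abort("an OTU cannot be both predator and prey: network must be bipartite")
  }
  structure(
    list(edges = as_tibble(edges), predator_nodes = predator_nodes,
         prey_nodes = prey_nodes, provenance = provenance),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  pv <- x$provenance
  cat("Bipartite predator-prey interaction network\n")
  if (!is.null(pv$site)) {
    cat("  context: site", paste(pv$site, collapse = "/"),
        "fraction", paste(pv$fraction, collapse = "/"), "\n")
  }
  cat("  screened:", length(x$predator_nodes), "predators x",
      length(x$prey_nodes), "prey\n")
  cat("  edges:", nrow(x$edges),
      sprintf("(gate tau < %s, p < %s)\n", pv$tau_max %||% "?", pv$alpha %||% "?"))
  invisible(x)
}

#' @describeIn infer_network edge list as a tibble.
#' @param x an `interaction_network`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.interaction_network <- function(x, ...) x$edges

#' @describeIn infer_network one-row network summary (node counts, edge
#'   count, sieve fraction, gates).
#' @exportS3Method generics::glance
glance.interaction_network <- function(x, ...) {
  tibble(
    n_predators = length(x$predator_nodes),
    n_prey = length(x$prey_nodes),
    n_edges = nrow(x$edges),
    sieve_fraction = sieve_fraction(x),
    tau_max = x$provenance$tau_max %||% NA_real_,
    alpha = x$provenance$alpha %||% NA_real_
  )
}

#' Fraction of possible predator-prey pairs sieved out
#'
#' The screen's selectivity: 1 - |edges| / (n_predators * n_prey). On the
#' study data the tau/p gate sieved more than 99.5% of possible connections.
#'
#' @param network an `interaction_network`.
#' @param n_predators,n_prey pair-universe dimensions; default to the
#'   screened node universes.
#' @return a number in [0, 1].
#' @export
sieve_fraction <- function(network, n_predators = length(network$predator_nodes),
                           n_prey = length(network$prey_nodes)) {
  if (n_predators * n_prey <= 0) abort("empty pair universe")
  1 - nrow(network$edges) / (n_predators * n_prey)
}

#' Convert an interaction network to an igraph graph
#'
#' @param network an `interaction_network`.
#' @param include_isolated include screened nodes with no edges.
#' @return undirected bipartite igraph object with vertex attributes
#'   `guild` (`"predator"`/`"prey"`), `type` and `degree`, and edge
#'   attributes `tau`, `p_value`.
#' @export
as_igraph <- function(network, include_isolated = FALSE) {
  preds <- network$predator_nodes
  prey <- network$prey_nodes
  if (!include_isolated) {
    preds <- intersect(preds, network$edges$predator_otu)
    prey <- intersect(prey, network$edges$prey_otu)
  }
  nodes <- tibble(
    name = c(preds, prey),
    guild = rep(c("predator", "prey"), c(length(preds), length(prey))),
    type = rep(c(FALSE, TRUE), c(length(preds), length(prey)))
  )
  g <- igraph::graph_from_data_frame(
    rename(network$edges, from = "predator_otu", to = "prey_otu"),
    directed = FALSE, vertices = nodes
  )
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Write the network edge list as TSV
#' @param network an `interaction_network`.
#' @param path output path.
#' @return `network`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(network$edges, path, progress = FALSE)
  invisible(network)
}

#' Export the network as GraphML
#'
#' Nodes carry `guild` and `degree` attributes; suitable for any graph
#' viewer.
#'
#' @param network an `interaction_network`.
#' @param path output path.
#' @param include_isolated include edge-less screened nodes.
#' @return `network`, invisibly.
#' @export
write_graphml <- function(network, path, include_isolated = FALSE) {
  igraph::write_graph(as_igraph(network, include_isolated), path, format = "graphml")
  invisible(network)
}
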