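star <- function(pred, prey) {
  tibble::tibble(predator_otu = pred, prey_otu = prey)
}

test_that("degree statistics use the standard error of the mean", {
  net <- make_network(star("bd1", paste0("q", 1:5)))
  ds <- degree_stats(net, "predator")
  expect_equal(ds$degree_mean, 5)
  expect_equal(ds$degree_se, 0)

  net2 <- make_network(dplyr::bind_rows(star("bd1", c("q1", "q2")),
                                        star("bd2", c("q3", "q4", "q5", "q6"))))
  ds2 <- degree_stats(net2, "predator")
  expect_equal(ds2$degree_mean, 3)
  expect_equal(ds2$degree_se, 1)  # sd(c(2,4))/sqrt(2)

  # a screened-but-unconnected predator contributes 0 when isolates count
  net3 <- make_network(star("bd1", c("q1", "q2")),
                       predator_nodes = c("bd1", "bd9"),
                       prey_nodes = c("q1", "q2"))
  expect_equal(degree_stats(net3, "predator", include_isolated = TRUE)$degree_mean, 1)
  expect_equal(degree_stats(net3, "predator")$degree_mean, 2)
})

test_that("predator and prey degrees both sum to the edge count", {
  set.seed(21)
  for (i in 1:5) {
    edges <- unique(tibble::tibble(
      predator_otu = sample(paste0("p", 1:6), 15, TRUE),
      prey_otu = sample(paste0("q", 1:10), 15, TRUE)))
    net <- make_network(edges)
    deg <- node_degrees(net)
    expect_equal(sum(deg$degree[deg$guild == "predator"]), nrow(edges))
    expect_equal(sum(deg$degree[deg$guild == "prey"]), nrow(edges))
  }
})

test_that("communities of disconnected stars are the components", {
  net <- make_network(dplyr::bind_rows(star("bd1", c("q1", "q2", "q3")),
                                       star("bd2", c("q4", "q5", "q6"))))
  part <- detect_communities(net, seed = 1)
  mem <- setNames(part$community, part$otu_id)
  expect_equal(length(unique(mem)), 2)
  expect_equal(unname(mem["q1"]), unname(mem["bd1"]))
  expect_equal(unname(mem["q4"]), unname(mem["bd2"]))
  expect_false(mem["bd1"] == mem["bd2"])
  # determinism under a fixed seed
  expect_equal(detect_communities(net, seed = 1), part)
})

test_that("K22 has no structure beyond the trivial partition", {
  net <- make_network(tidyr::expand_grid(predator_otu = c("bd1", "bd2"),
                                         prey_otu = c("q1", "q2")))
  part <- detect_communities(net, seed = 1)
  # exhaustive check: no partition of the 4 nodes beats the trivial Q = 0,
  # and the search achieves exactly that optimum
  edges <- as.matrix(net$edges[, c("predator_otu", "prey_otu")])
  best <- oracle_best_partition_q(edges, c("bd1", "bd2", "q1", "q2"))
  expect_lte(best, 0 + 1e-12)
  expect_equal(attr(part, "modularity"), 0)
})

test_that("modularity matches the direct Newman-Girvan formula", {
  set.seed(31)
  for (i in 1:5) {
    edges <- unique(tibble::tibble(
      predator_otu = sample(paste0("p", 1:4), 10, TRUE),
      prey_otu = sample(paste0("q", 1:6), 10, TRUE)))
    net <- make_network(edges)
    part <- detect_communities(net, seed = 2)
    mem <- setNames(part$community, part$otu_id)
    expect_equal(modularity_q(net, mem),
                 oracle_modularity(as.matrix(edges), mem), tolerance = 1e-12)
    # a single community always gives exactly 0
    one <- setNames(rep(1, length(mem)), names(mem))
    expect_equal(modularity_q(net, one), 0)
  }
})

test_that("greedy detection reaches the exhaustive optimum on small graphs", {
  set.seed(41)
  for (i in 1:4) {
    edges <- unique(tibble::tibble(
      predator_otu = sample(paste0("p", 1:3), 7, TRUE),
      prey_otu = sample(paste0("q", 1:5), 7, TRUE)))
    net <- make_network(edges)
    nodes <- c(unique(edges$predator_otu), unique(edges$prey_otu))
    if (length(nodes) > 8) next
    best <- oracle_best_partition_q(as.matrix(edges), nodes)
    got <- attr(detect_communities(net, seed = 1), "modularity")
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("random partitions of a random graph have near-zero modularity", {
  set.seed(51)
  g <- igraph::sample_gnp(80, 0.12)
  qs <- replicate(1000, modularity_q(g, sample(1:3, 80, TRUE)))
  expect_lt(abs(mean(qs)), 0.02)
})

test_that("path metrics follow hand-enumerated small cases", {
  path <- make_network(star("bd1", c("q1", "q2")))  # q1 - bd1 - q2
  pm <- path_metrics(path)
  expect_equal(pm$average_path_length, 4 / 3)
  expect_equal(pm$diameter, 2)
  expect_equal(pm$clustering_coefficient, 0)

  single <- make_network(star("bd1", "q1"))
  expect_equal(path_metrics(single)$diameter, 1)

  # bipartite graphs can have no triangles
  set.seed(61)
  edges <- unique(tibble::tibble(
    predator_otu = sample(paste0("p", 1:5), 12, TRUE),
    prey_otu = sample(paste0("q", 1:5), 12, TRUE)))
  expect_equal(path_metrics(make_network(edges))$clustering_coefficient, 0)
})

test_that("cumulative degree distribution starts at 1 and never rises", {
  net <- make_network(dplyr::bind_rows(star("bd1", "q1"), star("bd2", "q1")))
  # degrees: bd1 = 1, bd2 = 1, q1 = 2
  cdd <- cumulative_degree_distribution(net)
  expect_equal(cdd$p_geq[cdd$degree == 0], 1)
  expect_equal(cdd$p_geq[cdd$degree == 1], 1)
  expect_equal(cdd$p_geq[cdd$degree == 2], 1 / 3)
  set.seed(71)
  edges <- unique(tibble::tibble(
    predator_otu = sample(paste0("p", 1:6), 20, TRUE),
    prey_otu = sample(paste0("q", 1:8), 20, TRUE)))
  cdd2 <- cumulative_degree_distribution(make_network(edges))
  expect_equal(cdd2$p_geq[1], 1)
  expect_true(all(diff(cdd2$p_geq) <= 0))
})

test_that("network_topology bundles a consistent summary", {
  set.seed(81)
  edges <- unique(tibble::tibble(
    predator_otu = sample(paste0("p", 1:5), 15, TRUE),
    prey_otu = sample(paste0("q", 1:8), 15, TRUE)))
  net <- make_network(edges)
  topo <- network_topology(net, seed = 1)
  expect_s3_class(topo, "network_topology")
  g <- glance(topo)
  expect_lte(g$modularity_q, 1)
  expect_equal(g$n_nodes_predator + g$n_nodes_prey, nrow(tidy(topo)))
  expect_error(network_topology(make_network(edges[0, ], "p1", "q1")), "empty")
})
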