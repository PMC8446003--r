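# Small in-code fixtures and independent oracles shared across test files.

# 3-sample x 4-OTU community with one predator per clade and one
# gram-positive prey candidate.
toy_counts <- function() {
  m <- matrix(c(
    10, 5, 0, 3,
    2, 8, 4, 6,
    7, 1, 9, 2
  ), nrow = 3, byrow = TRUE)
  rownames(m) <- c("s1", "s2", "s3")
  colnames(m) <- c("bd1", "bx1", "preyA", "preyB")
  m
}

toy_meta <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    site = "SH", fraction = c("floc", "floc", "floc"),
    date = as.Date(c("2013-03-01", "2013-04-01", "2013-05-01")),
    temperature = c(18, 20, 23)
  )
}

toy_taxonomy <- function() {
  parse_taxonomy(
    c("Bacteria;Proteobacteria;Deltaproteobacteria;Bdellovibrionales;Bdellovibrionaceae;Bdellovibrio",
      "Bacteria;Proteobacteria;Deltaproteobacteria;Bacteriovoracales;Bacteriovoracaceae;Bacteriovorax",
      "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas",
      "Bacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus"),
    c("bd1", "bx1", "preyA", "preyB")
  )
}

toy_table <- function() {
  tx <- toy_taxonomy()
  otu_table(toy_counts(), toy_meta(), guilds = assign_guilds(tx),
            taxonomy = tx, mode = "raw_counts")
}

# random raw-count table: n_samples x n_otus, all prey candidates
random_table <- function(n_samples, n_otus, seed, lambda = 5,
                         sites = "SH", fractions = "floc") {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_otus, lambda), nrow = n_samples)
  rownames(m) <- sprintf("s%02d", seq_len(n_samples))
  colnames(m) <- sprintf("otu%03d", seq_len(n_otus))
  meta <- tibble::tibble(
    sample_id = rownames(m),
    site = rep(sites, length.out = n_samples),
    fraction = rep(fractions, length.out = n_samples),
    date = as.Date("2013-03-01") + seq_len(n_samples) * 7,
    temperature = 20 + rnorm(n_samples)
  )
  otu_table(m, meta, mode = "raw_counts")
}

# relative-mode tables for screening: predators x prey with given matrices
screen_tables <- function(X, Y) {
  n <- nrow(X)
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)), site = "SH", fraction = "floc",
    date = as.Date("2013-03-01") + seq_len(n) * 30, temperature = 20
  )
  rownames(X) <- rownames(Y) <- meta$sample_id
  Xr <- X / rowSums(X)
  Yr <- Y / rowSums(Y)
  list(
    predators = otu_table(Xr, meta,
                          guilds = setNames(rep("predator_bd", ncol(X)), colnames(X)),
                          mode = "relative"),
    prey = otu_table(Yr, meta, mode = "relative")
  )
}

# independent oracle: naive all-pairs screen by scalar double loop
oracle_screen <- function(X, Y, tau_max = -0.7, alpha = 0.01) {
  out <- list()
  for (i in seq_len(ncol(X))) {
    for (j in seq_len(ncol(Y))) {
      kt <- kendall_tau(X[, i], Y[, j])
      if (!is.na(kt$tau) && kt$tau < tau_max && kt$p_value < alpha) {
        out[[length(out) + 1]] <- tibble::tibble(
          predator_otu = colnames(X)[i], prey_otu = colnames(Y)[j],
          tau = kt$tau, p_value = kt$p_value)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(predator_otu = character(), prey_otu = character(),
                          tau = numeric(), p_value = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), predator_otu, prey_otu)
}

# independent modularity: direct Newman-Girvan formula on an edge list
oracle_modularity <- function(edges, membership) {
  m <- nrow(edges)
  nodes <- names(membership)
  deg <- setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(m)) {
    deg[edges[k, 1]] <- deg[edges[k, 1]] + 1
    deg[edges[k, 2]] <- deg[edges[k, 2]] + 1
  }
  q <- 0
  for (cc in unique(membership)) {
    inc <- names(membership)[membership == cc]
    e_c <- sum(edges[, 1] %in% inc & edges[, 2] %in% inc)
    d_c <- sum(deg[inc])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# exhaustive best-partition modularity for small graphs (set partitions)
oracle_best_partition_q <- function(edges, nodes) {
  partitions <- function(v) {
    if (length(v) == 1) return(list(list(v)))
    rest <- partitions(v[-1])
    out <- list()
    for (p in rest) {
      for (k in seq_along(p)) {
        q <- p
        q[[k]] <- c(v[1], q[[k]])
        out[[length(out) + 1]] <- q
      }
      out[[length(out) + 1]] <- c(list(v[1]), p)
    }
    out
  }
  best <- -Inf
  for (p in partitions(nodes)) {
    mem <- setNames(rep(seq_along(p), lengths(p)), unlist(p))
    best <- max(best, oracle_modularity(edges, mem[nodes]))
  }
  best
}

# network built directly from an edge tibble (bypasses screening)
make_network <- function(edges, predator_nodes = unique(edges$predator_otu),
                         prey_nodes = unique(edges$prey_otu)) {
  if (!"tau" %in% names(edges)) edges$tau <- -0.8
  if (!"p_value" %in% names(edges)) edges$p_value <- 0.001
  balonet:::new_interaction_network(edges, predator_nodes, prey_nodes,
                                    provenance = list(tau_max = -0.7, alpha = 0.01))
}
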