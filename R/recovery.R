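#' Score an inferred network against simulated ground truth
#'
#' Edge-set comparison on (predator, prey) identity: the truth is restricted
#' to the pair universe the screen actually examined (its predator and prey
#' node sets), then counted against the inferred edges. Precision and recall
#' are reported as `NA` when their denominators are zero, never as 0/0 = 0.
#'
#' @param inferred an `interaction_network`.
#' @param truth a `ground_truth` (or a tibble with `predator_otu`,
#'   `prey_otu` columns).
#' @return a `recovery_report`: one-row tibble with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `n_true_edges`, `n_inferred_edges` and
#'   the gate parameters.
#' @export
edge_recovery <- function(inferred, truth) {
  adj <- if (inherits(truth, "ground_truth")) truth$adjacency else as_tibble(truth)
  preds <- inferred$predator_nodes
  prey <- inferred$prey_nodes
  if (length(intersect(c(adj$predator_otu, adj$prey_otu), c(preds, prey))) == 0) {
    abort("inferred network and truth share no OTUs: disjoint universes")
  }
  truth_pairs <- adj %>%
    filter(.data$predator_otu %in% preds, .data$prey_otu %in% prey) %>%
    distinct(.data$predator_otu, .data$prey_otu)
  inf_pairs <- distinct(inferred$edges, .data$predator_otu, .data$prey_otu)
  key <- function(df) paste(df$predator_otu, df$prey_otu, sep = "\r")
  tp <- sum(key(inf_pairs) %in% key(truth_pairs))
  fp <- nrow(inf_pairs) - tp
  fn <- nrow(truth_pairs) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  out <- tibble(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    n_true_edges = nrow(truth_pairs), n_inferred_edges = nrow(inf_pairs),
    tau_max = inferred$provenance$tau_max %||% NA_real_,
    alpha = inferred$provenance$alpha %||% NA_real_
  )
  class(out) <- c("recovery_report", class(out))
  out
}

#' Sweep the tau/alpha gate and score each operating point
#'
#' Re-screens nothing: correlations are computed once and re-gated for
#' every (tau_max, alpha) combination, then scored against the truth.
#'
#' @param predators,prey relative-mode `otu_tbl`s as in [infer_network()].
#' @param truth a `ground_truth` or truth edge tibble.
#' @param tau_grid,alpha_grid numeric grids of gate values.
#' @return tibble with one recovery row per (tau_max, alpha).
#' @export
threshold_sweep <- function(predators, prey, truth,
                            tau_grid = c(-0.9, -0.8, -0.7, -0.6),
                            alpha_grid = c(0.01, 0.05)) {
  if (length(tau_grid) == 0 || length(alpha_grid) == 0) abort("empty grid")
  X <- otu_matrix(predators)
  Y <- otu_matrix(prey)
  scr <- kendall_screen(X, Y)
  grid <- tidyr::expand_grid(tau_max = tau_grid, alpha = alpha_grid)
  purrr::pmap_dfr(grid, function(tau_max, alpha) {
    hit <- which(!is.na(scr$tau) & scr$tau < tau_max & scr$p < alpha, arr.ind = TRUE)
    net <- new_interaction_network(
      tibble(predator_otu = colnames(X)[hit[, 1]], prey_otu = colnames(Y)[hit[, 2]],
             tau = scr$tau[hit], p_value = scr$p[hit]),
      predator_nodes = colnames(X), prey_nodes = colnames(Y),
      provenance = list(tau_max = tau_max, alpha = alpha)
    )
    edge_recovery(net, truth)
  })
}
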