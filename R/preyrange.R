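#' Prey ranges of each predator
#'
#' The prey range of a predator OTU is the set of prey OTUs it is connected
#' to in the inferred network. Predators with no connections are excluded.
#'
#' @param network an `interaction_network`.
#' @return a `prey_range_set`: tibble with `predator_otu`, `prey_otus`
#'   (list-column of prey id sets) and `n_prey`, plus the network context as
#'   a `"context"` attribute.
#' @export
prey_sets <- function(network) {
  if (nrow(network$edges) == 0) abort("network has no edges: no prey ranges")
  out <- network$edges %>%
    group_by(.data$predator_otu) %>%
    summarise(prey_otus = list(sort(unique(.data$prey_otu)))) %>%
    mutate(n_prey = lengths(.data$prey_otus)) %>%
    arrange(.data$predator_otu)
  attr(out, "context") <- network$provenance
  class(out) <- c("prey_range_set", class(out))
  out
}

#' Venn overlap of two or three id collections
#'
#' Region counts and percentages for prey-range (or any OTU-set)
#' comparisons, in the style of GenVenn output. Percentages are of the
#' union, rounded half-up to one decimal.
#'
#' @param sets named list of 2 or 3 character vectors (duplicates ignored).
#' @return tibble with `region` (e.g. `"a_only"`, `"a_and_b"`, `"all"`),
#'   `count` and `pct_of_union`.
#' @export
venn_overlap <- function(sets) {
  if (!length(sets) %in% c(2, 3)) abort("venn_overlap takes 2 or 3 sets")
  sets <- lapply(sets, unique)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- letters[seq_along(sets)]
  }
  universe <- unique(unlist(sets))
  if (length(universe) == 0) abort("empty union: nothing to overlap")
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- unlist(combos[i, ])
    hit <- rowSums(member[, inc, drop = FALSE]) == sum(inc) &
      rowSums(member[, !inc, drop = FALSE]) == 0
    nm <- if (all(inc)) "all" else
      paste0(paste(names(sets)[inc], collapse = "_and_"), "_only")
    tibble(region = nm, count = sum(hit))
  })
  out <- bind_rows(rows) %>%
    mutate(pct_of_union = round_half_up(100 * .data$count / length(universe), 1)) %>%
    arrange(dplyr::desc(.data$count))
  attr(out, "n_union") <- length(universe)
  out
}

#' Shared percentage of a count over a reference
#'
#' `100 * n_shared / n_reference`, rounded half-up to one decimal — the form
#' in which shared-OTU statistics are printed (e.g. 90/133 -> 67.7).
#'
#' @param n_shared,n_reference counts.
#' @return percentage, one decimal.
#' @export
shared_percentage <- function(n_shared, n_reference) {
  if (any(n_reference <= 0)) abort("reference count must be positive")
  round_half_up(100 * n_shared / n_reference, 1)
}

#' Pairwise overlap of two id sets with both printed denominators
#'
#' Shared-OTU reports mix two denominators: the shared count over the
#' pairwise union, and over a single reference collection's total. Both are
#' computed and labeled.
#'
#' @param set_a,set_b character vectors of ids.
#' @return tibble with `n_shared`, `n_union`, `n_a`, `n_b`,
#'   `pct_of_union`, `pct_of_a`, `pct_of_b`.
#' @export
overlap_pair <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) + length(set_b) == 0) abort("empty union: nothing to overlap")
  shared <- length(intersect(set_a, set_b))
  uni <- length(union(set_a, set_b))
  tibble(
    n_shared = shared, n_union = uni,
    n_a = length(set_a), n_b = length(set_b),
    pct_of_union = shared_percentage(shared, uni),
    pct_of_a = if (length(set_a) > 0) shared_percentage(shared, length(set_a)) else NA_real_,
    pct_of_b = if (length(set_b) > 0) shared_percentage(shared, length(set_b)) else NA_real_
  )
}

#' Percentage of prey hunted by exactly one predator
#'
#' How strongly predators partition the prey pool: 100 x (prey OTUs
#' appearing in exactly one predator's range) / (distinct prey OTUs across
#' all ranges).
#'
#' @param range_set a `prey_range_set` from [prey_sets()].
#' @return percentage (not rounded).
#' @export
unique_prey_fraction <- function(range_set) {
  if (nrow(range_set) < 2) abort("need at least 2 predators")
  prey <- unlist(range_set$prey_otus)
  counts <- table(prey)
  100 * sum(counts == 1) / length(counts)
}

#' Association between predator degree and abundance
#'
#' Pearson r-squared between each predator's mean relative abundance over
#' the series and its number of prey connections. Near-zero values say that
#' hub predators are not simply the abundant ones.
#'
#' @param network an `interaction_network`.
#' @param table `otu_tbl` in relative mode containing the predator series.
#' @param guild `"predator_bd"`, `"predator_bx"` or `"all"` predators.
#' @return one-row tibble with `guild`, `n`, `r`, `r_squared` (`NA` when a
#'   variable has zero variance).
#' @export
degree_abundance_correlation <- function(network, table, guild = "all") {
  stop_if_not_otu(table)
  deg <- node_degrees(network, include_isolated = FALSE) %>%
    filter(.data$guild == "predator")
  info <- otu_info(table)
  if (guild != "all") {
    deg <- filter(deg, .data$otu_id %in% info$otu_id[info$guild == !!guild])
  }
  missing <- setdiff(deg$otu_id, info$otu_id)
  if (length(missing) > 0) {
    abort(paste0("predators absent from the abundance table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (nrow(deg) < 3) abort("need at least 3 predators")
  ab <- as_tibble(table) %>%
    filter(.data$otu_id %in% deg$otu_id) %>%
    group_by(.data$otu_id) %>%
    summarise(mean_abundance = mean(.data$count))
  joined <- left_join(deg, ab, by = "otu_id")
  if (sd(joined$degree) == 0 || sd(joined$mean_abundance) == 0) {
    return(tibble(guild = guild, n = nrow(joined), r = NA_real_, r_squared = NA_real_))
  }
  r <- cor(joined$mean_abundance, joined$degree)
  tibble(guild = guild, n = nrow(joined), r = r, r_squared = r^2)
}
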