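#' Alpha diversity of a count or abundance vector
#'
#' Shannon H = -sum p ln p, Gini-Simpson 1 - sum p^2, richness = number of
#' nonzero entries, Pielou evenness = H / ln(richness) (1 for a single OTU
#' by convention being undefined, reported as NA).
#'
#' @param counts non-negative vector with positive total, or an `otu_tbl`
#'   (then computed per sample).
#' @return one-row tibble (`shannon`, `simpson`, `richness`, `evenness`),
#'   or one row per sample for an `otu_tbl`.
#' @export
alpha_diversity <- function(counts) {
  if (inherits(counts, "otu_tbl")) {
    m <- otu_matrix(counts)
    return(bind_rows(lapply(rownames(m), function(s) {
      dplyr::bind_cols(tibble(sample_id = s), alpha_diversity(m[s, ]))
    })))
  }
  if (any(counts < 0)) abort("negative abundances")
  tot <- sum(counts)
  if (tot <= 0) abort("all-zero vector: diversity undefined")
  p <- counts[counts > 0] / tot
  h <- -sum(p * log(p))
  rich <- length(p)
  tibble(
    shannon = h,
    simpson = 1 - sum(p^2),
    richness = rich,
    evenness = if (rich > 1) h / log(rich) else NA_real_
  )
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' 1 - 2 sum min(x, y) / (sum x + sum y), in [0, 1]. Symmetric and bounded
#' but only a semi-metric (no triangle inequality).
#'
#' @param x,y non-negative vectors of equal length, not both all-zero.
#' @return a number in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) abort("negative abundances")
  if (sum(x) + sum(y) <= 0) abort("both vectors all-zero: distance undefined")
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Bray-Curtis distance matrix of an OTU table
#'
#' @param table an `otu_tbl` (any mode); samples in time order.
#' @return a `dist` object over samples (via [vegan::vegdist()]).
#' @export
bray_curtis_matrix <- function(table) {
  stop_if_not_otu(table)
  vegan::vegdist(otu_matrix(table), method = "bray")
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers -D^2/2 and eigendecomposes it; coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues.
#' Negative eigenvalues (from semi-metric distances such as Bray-Curtis)
#' are reported but excluded from the proportion explained; no Cailliez or
#' Lingoes correction is applied.
#'
#' @param distances a `dist` or symmetric square matrix with zero diagonal.
#' @param k number of axes to return (default 2, capped at the number of
#'   positive eigenvalues).
#' @return a `pcoa_result` with `coordinates` (samples x axes),
#'   `eigenvalues` (all, sorted), `proportion_explained` (per returned
#'   axis); has [tidy()], [glance()] and [autoplot()] methods.
#' @export
pcoa <- function(distances, k = 2) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("distance matrix must be square and symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix must have a zero diagonal")
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- which(eig$values > 1e-12 * max(abs(eig$values), 1))
  k_eff <- min(k, length(pos))
  coords <- if (k_eff > 0) {
    sweep(eig$vectors[, pos[seq_len(k_eff)], drop = FALSE], 2,
          sqrt(eig$values[pos[seq_len(k_eff)]]), `*`)
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(d)
  if (k_eff > 0) colnames(coords) <- paste0("axis", seq_len(k_eff))
  prop <- if (length(pos) > 0) {
    eig$values[pos[seq_len(k_eff)]] / sum(eig$values[pos])
  } else {
    numeric(0)
  }
  structure(list(coordinates = coords, eigenvalues = eig$values,
                 proportion_explained = prop),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", ncol(x$coordinates), "axes\n")
  if (length(x$proportion_explained) > 0) {
    cat("  proportion explained:",
        paste(format(100 * x$proportion_explained, digits = 3), collapse = "%, "),
        "%\n")
  }
  invisible(x)
}

#' @describeIn pcoa sample coordinates as a tibble.
#' @param x a `pcoa_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.pcoa_result <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = rownames(x$coordinates)),
                   as_tibble(x$coordinates))
}

#' @describeIn pcoa eigenvalue summary.
#' @exportS3Method generics::glance
glance.pcoa_result <- function(x, ...) {
  tibble(
    n_axes = ncol(x$coordinates),
    n_positive_eigenvalues = sum(x$eigenvalues > 1e-12 * max(abs(x$eigenvalues), 1)),
    n_negative_eigenvalues = sum(x$eigenvalues < -1e-12 * max(abs(x$eigenvalues), 1)),
    prop_axis1 = if (length(x$proportion_explained) >= 1) x$proportion_explained[1] else NA_real_,
    prop_axis2 = if (length(x$proportion_explained) >= 2) x$proportion_explained[2] else NA_real_
  )
}

#' Multi-response permutation procedure (MRPP)
#'
#' Tests whether within-group community distances are smaller than expected
#' under random group assignment. The observed delta is the group-size
#' weighted (n_g / N) mean within-group distance; the chance-corrected
#' within-group agreement is A = 1 - delta_obs / mean(delta_perm), and
#' p = (1 + #\{delta_perm <= delta_obs\}) / (1 + n_permutations). With
#' `exact = TRUE` all distinct label assignments are enumerated instead
#' (feasible for small groups), and p is the exact tail fraction including
#' the observed assignment.
#'
#' @param distances a `dist` or symmetric square matrix.
#' @param groups group labels, one per sample; every group needs >= 2
#'   members.
#' @param n_permutations number of label permutations (ignored when exact).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all label assignments instead of sampling.
#' @return an `mrpp_result` with `a_statistic`, `observed_delta`,
#'   `expected_delta`, `p_value`, `n_permutations`; [glance()] returns it
#'   as a one-row tibble.
#' @export
mrpp <- function(distances, groups, n_permutations = 999, seed = 1,
                 exact = FALSE) {
  d <- as.matrix(distances)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) abort("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort(paste0("groups of size 1 are not allowed: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  delta_of <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      s <- s + length(idx) / length(lab) * mean(d[idx, idx][upper.tri(diag(length(idx)))])
    }
    s
  }
  obs <- delta_of(groups)
  if (exact) {
    assignments <- enumerate_assignments(groups)
    deltas <- vapply(assignments, delta_of, numeric(1))
    expected <- mean(deltas)
    p <- mean(deltas <= obs + 1e-12)
    n_perm <- length(deltas)
  } else {
    deltas <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
      delta_of(sample(groups))
    }, numeric(1)))
    expected <- mean(deltas)
    p <- (1 + sum(deltas <= obs + 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(
    a_statistic = 1 - obs / expected,
    observed_delta = obs,
    expected_delta = expected,
    p_value = p,
    n_permutations = n_perm,
    exact = exact
  ), class = "mrpp_result")
}

# all distinct assignments of the multiset of labels to positions
enumerate_assignments <- function(groups) {
  n <- length(groups)
  labs <- sort(unique(groups))
  out <- list(rep(NA_character_, n))
  free <- list(seq_len(n))
  for (g in labs[-length(labs)]) {
    k <- sum(groups == g)
    new_out <- list()
    new_free <- list()
    for (i in seq_along(out)) {
      picks <- combn(free[[i]], k, simplify = FALSE)
      for (p in picks) {
        lab <- out[[i]]
        lab[p] <- g
        new_out[[length(new_out) + 1]] <- lab
        new_free[[length(new_free) + 1]] <- setdiff(free[[i]], p)
      }
    }
    out <- new_out
    free <- new_free
  }
  lapply(seq_along(out), function(i) {
    lab <- out[[i]]
    lab[free[[i]]] <- labs[length(labs)]
    lab
  })
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat("MRPP: A =", format(x$a_statistic, digits = 3),
      " delta_obs =", format(x$observed_delta, digits = 4),
      " p =", format(x$p_value, digits = 3),
      if (x$exact) "(exact enumeration)" else
        sprintf("(%d permutations)", x$n_permutations), "\n")
  invisible(x)
}

#' @describeIn mrpp one-row tibble of the MRPP result.
#' @param x an `mrpp_result`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.mrpp_result <- function(x, ...) {
  tibble(a_statistic = x$a_statistic, observed_delta = x$observed_delta,
         expected_delta = x$expected_delta, p_value = x$p_value,
         n_permutations = x$n_permutations, exact = x$exact)
}

#' Two-sample Kolmogorov-Smirnov test on rank-abundance samples
#'
#' Compares two OTU rank-abundance distributions (typically restricted
#' upstream to OTUs above 0.1% relative abundance). D is the supremum
#' distance between the two empirical CDFs of abundance values; p is exact
#' for small samples without ties, asymptotic otherwise (via
#' [stats::ks.test()]).
#'
#' @param x,y positive abundance vectors (one value per OTU).
#' @return one-row tibble with `d_statistic`, `p_value`, `n_x`, `n_y`.
#' @export
ks_rank_abundance <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("empty abundance vector")
  kt <- suppressWarnings(stats::ks.test(x, y))
  tibble(d_statistic = unname(kt$statistic), p_value = kt$p.value,
         n_x = length(x), n_y = length(y))
}

#' Per-OTU correlation with an environmental series
#'
#' Pearson r of each OTU's abundance series against an aligned
#' environmental series (typically temperature), plus the mean and sample
#' standard deviation (n - 1) of |r| over a stated OTU subset — the form in
#' which seasonal temperature linkage is summarized.
#'
#' @param table an `otu_tbl`; the environmental series defaults to its
#'   `temperature` metadata.
#' @param env optional numeric series, one value per sample in time order.
#' @param otus OTU subset to aggregate over (default: all OTUs in `table`).
#' @return list with `per_otu` (tibble `otu_id`, `r`; constant series are
#'   skipped and reported in `skipped`) and `aggregate` (one-row tibble
#'   `mean_abs_r`, `sd_abs_r`, `n_otus`).
#' @export
env_correlation <- function(table, env = NULL, otus = NULL) {
  stop_if_not_otu(table)
  meta <- sample_info(table)
  if (is.null(env)) env <- meta$temperature
  if (length(env) != nrow(meta)) abort("`env` must have one value per sample")
  if (anyNA(env)) abort("environmental series has missing values")
  if (nrow(meta) < 3) abort("need at least 3 time points")
  if (sd(env) == 0) abort("environmental series has zero variance")
  m <- otu_matrix(table)
  if (is.null(otus)) otus <- colnames(m)
  missing <- setdiff(otus, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("OTUs absent from table: ", paste(head(missing, 5), collapse = ", ")))
  }
  sds <- apply(m[, otus, drop = FALSE], 2, sd)
  skipped <- otus[sds == 0]
  keep <- otus[sds > 0]
  r <- vapply(keep, function(o) cor(m[, o], env), numeric(1))
  per_otu <- tibble(otu_id = keep, r = unname(r))
  agg <- tibble(
    mean_abs_r = mean(abs(per_otu$r)),
    sd_abs_r = if (nrow(per_otu) > 1) sd(abs(per_otu$r)) else NA_real_,
    n_otus = nrow(per_otu)
  )
  list(per_otu = per_otu, aggregate = agg, skipped = skipped)
}
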