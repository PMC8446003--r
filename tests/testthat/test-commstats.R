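test_that("alpha diversity matches closed forms", {
  u4 <- alpha_diversity(rep(25, 4))
  expect_equal(u4$shannon, log(4))
  expect_equal(u4$evenness, 1)
  expect_equal(u4$richness, 4)

  single <- alpha_diversity(c(0, 42, 0))
  expect_equal(single$shannon, 0)
  expect_equal(single$simpson, 0)
  expect_equal(single$richness, 1)
  expect_true(is.na(single$evenness))

  p <- c(5, 3, 2) / 10
  hand <- alpha_diversity(c(5, 3, 2))
  expect_equal(hand$shannon, -sum(p * log(p)))
  expect_equal(hand$simpson, 1 - sum(p^2))
  expect_error(alpha_diversity(c(0, 0)), "all-zero")

  # per-sample over a table, cross-checked against vegan
  tbl <- random_table(5, 12, seed = 3)
  per <- alpha_diversity(tbl)
  expect_equal(per$shannon,
               unname(vegan::diversity(otu_matrix(tbl), index = "shannon")))
  expect_equal(per$simpson,
               unname(vegan::diversity(otu_matrix(tbl), index = "simpson")))
})

test_that("Bray-Curtis follows its formula and vegan agrees", {
  expect_equal(bray_curtis(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(1, 1, 0), c(0, 1, 1)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")

  set.seed(13)
  for (i in 1:5) {
    x <- runif(8)
    y <- runif(8)
    d <- bray_curtis(x, y)
    expect_equal(d, bray_curtis(y, x))
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d, as.numeric(vegan::vegdist(rbind(x, y), "bray")))
  }

  tbl <- random_table(4, 10, seed = 17)
  m <- otu_matrix(tbl)
  expect_equal(as.matrix(bray_curtis_matrix(tbl))["s01", "s03"],
               bray_curtis(m["s01", ], m["s03", ]))
})

test_that("PCoA reconstructs Euclidean configurations", {
  pts <- c(0, 1, 3.5)
  D <- as.matrix(dist(pts))
  pc <- pcoa(D, k = 2)
  expect_lt(max(abs(as.matrix(dist(pc$coordinates)) - D)), 1e-9)
  expect_equal(ncol(pc$coordinates), 1)  # collinear: one positive eigenvalue

  same <- matrix(0, 3, 3)
  pc0 <- pcoa(same, k = 2)
  expect_equal(ncol(pc0$coordinates), 0)

  tri <- matrix(1, 3, 3) - diag(3)  # equilateral triangle
  pct <- pcoa(tri, k = 2)
  ev <- pct$eigenvalues[pct$eigenvalues > 1e-9]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2])
  expect_true(all(abs(pct$proportion_explained - 0.5) < 1e-9))

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
})

test_that("MRPP permutation p and A behave as defined and vegan agrees on delta", {
  set.seed(23)
  x <- rbind(matrix(rnorm(8, 0), 4), matrix(rnorm(8, 4), 4))
  d <- dist(x)
  g <- rep(c("a", "b"), each = 4)
  res <- mrpp(d, g, n_permutations = 499, seed = 2)
  v <- suppressMessages(vegan::mrpp(d, g, permutations = 499))
  expect_equal(res$observed_delta, v$delta)
  expect_gt(res$a_statistic, 0)
  expect_lte(res$p_value, 0.05)

  # two tight clusters with zero within-group spread -> A = 1
  y <- rbind(matrix(1, 3, 2), matrix(9, 3, 2))
  rz <- mrpp(dist(y), rep(c("a", "b"), each = 3), n_permutations = 99, seed = 1)
  expect_equal(rz$a_statistic, 1)

  # homogeneous cloud -> A near 0
  set.seed(29)
  cloud <- matrix(rnorm(80), 40)
  ra <- mrpp(dist(cloud), sample(rep(c("a", "b"), 20)), n_permutations = 199, seed = 3)
  expect_lt(abs(ra$a_statistic), 0.05)

  expect_error(mrpp(dist(cloud[1:5, ]), c("a", "a", "a", "a", "b")), "size 1")
})

test_that("exact MRPP enumerates all 20 assignments of 6 samples", {
  set.seed(37)
  x <- matrix(rnorm(12), 6)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 3)
  res <- mrpp(d, g, exact = TRUE)
  expect_equal(res$n_permutations, 20)

  # independent oracle: loop over combn(6, 3)
  delta <- function(lab) {
    s <- 0
    for (gg in c("a", "b")) {
      idx <- which(lab == gg)
      s <- s + (3 / 6) * mean(d[idx, idx][upper.tri(diag(3))])
    }
    s
  }
  picks <- combn(6, 3)
  deltas <- apply(picks, 2, function(p) {
    lab <- rep("b", 6); lab[p] <- "a"; delta(lab)
  })
  expect_equal(res$observed_delta, delta(g))
  expect_equal(res$p_value, mean(deltas <= delta(g) + 1e-12))
  expect_equal(res$a_statistic, 1 - delta(g) / mean(deltas))
})

test_that("rank-abundance KS test wraps the exact two-sample statistic", {
  same <- ks_rank_abundance(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$d_statistic, 0)
  sep <- ks_rank_abundance(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$d_statistic, 1)
  expect_equal(sep$p_value, 0.1)  # 2 of the 20 orderings are this extreme
  expect_error(ks_rank_abundance(numeric(), 1:3), "empty")
})

test_that("environmental correlations aggregate |r| with sample sd", {
  n <- 12
  temp <- seasonal_temperature(seq(0, 330, 30))
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n), site = "SH", fraction = "floc",
    date = as.Date("2013-03-01") + seq(0, 330, 30), temperature = temp)
  m <- cbind(warm = temp, cold = max(temp) - temp + 1, flat = rep(3, n))
  rownames(m) <- meta$sample_id
  tbl <- otu_table(m, meta, mode = "raw_counts")
  out <- env_correlation(tbl)
  expect_equal(out$per_otu$r[out$per_otu$otu_id == "warm"], 1)
  expect_equal(out$per_otu$r[out$per_otu$otu_id == "cold"], -1)
  expect_equal(out$skipped, "flat")
  expect_equal(out$aggregate$mean_abs_r, 1)

  # aggregate over a stated subset with documented n-1 dispersion
  m2 <- cbind(a = temp + rnorm(n, 0, 6), b = -temp + rnorm(n, 0, 6))
  rownames(m2) <- meta$sample_id
  m2 <- m2 - min(m2) + 1
  tbl2 <- otu_table(m2, meta, mode = "raw_counts")
  out2 <- env_correlation(tbl2, otus = c("a", "b"))
  r <- vapply(c("a", "b"), function(o) cor(m2[, o], temp), numeric(1))
  expect_equal(out2$aggregate$mean_abs_r, mean(abs(r)))
  expect_equal(out2$aggregate$sd_abs_r, sd(abs(r)))
})
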