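test_that("seasonal temperature is a clean yearly sinusoid", {
  t <- 0:364
  flat <- seasonal_temperature(t, mean = 20, amplitude = 0)
  expect_true(all(flat == 20))
  s <- seasonal_temperature(t, mean = 20, amplitude = 6, phase = 64)
  expect_equal(seasonal_temperature(10), seasonal_temperature(10 + 365))
  expect_equal(max(s) - min(s), 12, tolerance = 1e-3)
  expect_error(seasonal_temperature(t, amplitude = -1), "non-negative")
})

quiet_config <- function(...) {
  args <- list(n_prey = 12, n_predators_bd = 2, n_predators_bx = 2,
               interaction_density = 0, process_noise_sd = 0,
               predator_noise_sd = 0, seasonal_amplitude = c(0, 0),
               fast_amplitude = c(0, 0), prey_seasonal_amplitude = c(0, 0),
               prey_capacity_sigma = 0.3)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

test_that("without predation or noise, prey settle at capacity and predators starve", {
  truth <- simulate_dynamics(quiet_config(), seed = 5)
  expect_equal(nrow(truth$adjacency), 0)
  lat <- truth$compartments[[1]]$latent
  g <- setNames(truth$otus$guild, truth$otus$otu_id)
  pred_cols <- colnames(lat)[g[colnames(lat)] != "prey_candidate"]
  prey_cols <- setdiff(colnames(lat), pred_cols)
  # predators decay to the extinction floor
  expect_lt(max(lat[nrow(lat), pred_cols]), 1e-6)
  # prey fixed point: trajectories flat across the year (the residual drift
  # is the decaying predators leaving the relative-abundance denominator)
  rel_range <- apply(lat[, prey_cols], 2, function(v) diff(range(v)) / mean(v))
  expect_lt(max(rel_range), 1e-4)
})

test_that("the same seed reproduces the run; different seeds do not", {
  cfg <- sim_config(n_prey = 30, n_predators_bd = 3, n_predators_bx = 3)
  a <- simulate_dynamics(cfg, seed = 9)
  b <- simulate_dynamics(cfg, seed = 9)
  expect_equal(a$compartments[[1]]$latent, b$compartments[[1]]$latent)
  expect_equal(a$adjacency, b$adjacency)
  c2 <- simulate_dynamics(cfg, seed = 10)
  expect_false(isTRUE(all.equal(a$compartments[[1]]$latent,
                                c2$compartments[[1]]$latent)))
})

test_that("predators oscillate on weekly-to-seasonal scales at study defaults", {
  truth <- simulate_dynamics(sim_config(), seed = 2)
  lat <- truth$compartments[["S1.floc"]]$latent
  g <- setNames(truth$otus$guild, truth$otus$otu_id)
  pred_cols <- colnames(lat)[g[colnames(lat)] != "prey_candidate"]
  det <- sweep(lat[, pred_cols], 2, colMeans(lat[, pred_cols]))
  sign_changes <- apply(det, 2, function(v) sum(diff(sign(v)) != 0))
  expect_gte(median(sign_changes), 4)
})

test_that("gram-positive prey are never preyed upon", {
  for (sd in 1:3) {
    truth <- simulate_dynamics(sim_config(fraction_gram_positive = 0.5), seed = sd)
    gp <- truth$otus$otu_id[truth$otus$gram_positive]
    expect_length(intersect(truth$adjacency$prey_otu, gp), 0)
    # and the synthetic taxonomy marks exactly those OTUs gram-positive
    tx <- truth$taxonomy
    expect_setequal(tx$otu_id[tx$phylum %in% c("Firmicutes", "Actinobacteria")], gp)
  }
})

test_that("read sampling conserves depth and respects zero abundances", {
  cfg <- sim_config(n_prey = 15, n_predators_bd = 2, n_predators_bx = 2)
  truth <- simulate_dynamics(cfg, seed = 6)
  tbl <- sample_reads(truth, depth = 700, seed = 7)
  sums <- tapply(tbl$count, tbl$sample_id, sum)
  expect_true(all(sums == 700))

  # an OTU absent from the latent pool never draws reads
  cmp <- truth$compartments[["S1.floc"]]
  zero_otus <- colnames(cmp$latent)[colMeans(cmp$latent) == 0]
  if (length(zero_otus) > 0) {
    floc <- dplyr::filter(tbl, fraction == "floc", otu_id %in% zero_otus)
    expect_true(all(floc$count == 0))
  }

  # multinomial mean matches the latent proportion within 3 MC sd
  p_target <- cmp$latent[1, ]
  top <- names(sort(p_target, decreasing = TRUE))[1]
  draws <- with_seed_draws <- sapply(1:200, function(i) {
    t2 <- sample_reads(truth, depth = 700, seed = 1000 + i)
    f <- dplyr::filter(t2, fraction == "floc")
    s1 <- sort(unique(f$sample_id))[1]
    f$count[f$sample_id == s1 & f$otu_id == top] / 700
  })
  mc_sd <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - p_target[top]), 3 * mc_sd + 1e-4)
})

test_that("the three study pools cover the right OTUs at the right depths", {
  cfg <- sim_config(n_prey = 20, n_predators_bd = 3, n_predators_bx = 3)
  truth <- simulate_dynamics(cfg, seed = 8)
  pools <- sample_study_reads(truth, depth = 600, predator_depth = 400, seed = 9)
  expect_named(pools, c("total", "bd", "bx"))
  g <- setNames(truth$otus$guild, truth$otus$otu_id)
  expect_true(all(g[unique(pools$bd$otu_id)] == "predator_bd"))
  expect_true(all(g[unique(pools$bx$otu_id)] == "predator_bx"))
  expect_true(all(tapply(pools$bd$count, pools$bd$sample_id, sum) == 400))
  expect_true(all(tapply(pools$total$count, pools$total$sample_id, sum) == 600))
})

test_that("the desk design simulates and samples quickly with predators at trace abundance", {
  t0 <- Sys.time()
  truth <- simulate_dynamics(default_study_design("desk"), seed = 123)
  tbl <- sample_reads(truth, seed = 124)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 60)

  m <- otu_matrix(dplyr::filter(tbl, site == "S1", fraction == "floc") |>
                    balonet:::restore_otu(tbl))
  g <- setNames(truth$otus$guild, truth$otus$otu_id)
  pred_cols <- colnames(m)[g[colnames(m)] != "prey_candidate"]
  frac <- rowSums(m[, pred_cols]) / rowSums(m)
  expect_gt(median(frac), 0.001)
  expect_lt(median(frac), 0.01)
})

test_that("predators respond positively to prey availability", {
  # shallow-suppression one-predator/one-prey pair: the predator equilibrium
  # rises with the prey's carrying capacity
  pair_cfg <- function(K) {
    quiet_config(n_prey = 1, n_predators_bd = 1, n_predators_bx = 0,
                 interaction_density = 1, ktw_exponent = 0,
                 attack_rate = c(3000, 3000), conversion = 4e-5,
                 decay_rate = c(0.06, 0.06), prey_overlap_fraction = 1,
                 burn_in = 200, carrying_capacity = K)
  }
  base <- pair_cfg(1)
  rich <- pair_cfg(2)
  y_base <- simulate_dynamics(base, seed = 1)$compartments[[1]]$latent[18, 2]
  y_rich <- simulate_dynamics(rich, seed = 1)$compartments[[1]]$latent[18, 2]
  expect_gt(y_rich, y_base)
})

test_that("latent tables expose clean relative compositions", {
  truth <- simulate_dynamics(sim_config(n_prey = 30, n_predators_bd = 3,
                                        n_predators_bx = 3), seed = 31)
  tabs <- latent_tables(truth, "S1.floc")
  expect_equal(table_mode(tabs$predators), "relative")
  sums <- tapply(tabs$predators$count, tabs$predators$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  info <- otu_info(tabs$prey)
  expect_true(all(info$guild == "prey_candidate"))
  gp <- truth$otus$otu_id[truth$otus$gram_positive]
  expect_length(intersect(info$otu_id, gp), 0)
})

test_that("a simulation can be written out and re-read as a study dataset", {
  cfg <- sim_config(n_prey = 10, n_predators_bd = 2, n_predators_bx = 2)
  truth <- simulate_dynamics(cfg, seed = 41)
  tbl <- sample_reads(truth, depth = 300, seed = 42)
  dir <- withr::local_tempdir()
  write_simulation(truth, tbl, dir)
  back <- read_otu_table(file.path(dir, "counts.tsv"),
                         file.path(dir, "taxonomy.tsv"),
                         file.path(dir, "metadata.tsv"))
  expect_equal(otu_matrix(back), otu_matrix(tbl))
  adj <- readr::read_tsv(file.path(dir, "truth_adjacency.tsv"), show_col_types = FALSE)
  expect_equal(nrow(adj), nrow(truth$adjacency))
})
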