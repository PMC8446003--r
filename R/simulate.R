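#' Simulation configuration for a predator-prey community
#'
#' Parameters of the generative model: a discrete-time (Ricker-type)
#' stochastic generalized Lotka-Volterra community of gram-negative and
#' gram-positive prey plus two guilds of obligate predators
#' (Bdellovibrionales-like `bd`, Bacteriovoracales-like `bx`). Predation
#' coefficients touch only (predator, gram-negative prey) pairs — obligate
#' predators of this kind attack gram-negative cells only. Predators decay
#' without prey (`decay_rate`), convert consumed prey into growth
#' (`conversion`), and carry an individual forcing made of an annual
#' component phase-jittered around the temperature peak plus two sub-annual
#' components with their own periods, producing oscillations from weeks to
#' season. Prey grow logistically, each toward its own niche size drawn
#' from a log-normal species-abundance distribution.
#'
#' Dynamics run on a daily internal grid and are observed at
#' `observation_days` (default: the 18-point yearly design of 12 monthly
#' samples plus two runs of extra weekly samples in late summer and late
#' winter).
#'
#' @param n_prey number of prey OTUs per site.
#' @param n_predators_bd,n_predators_bx predator OTUs per guild.
#' @param fraction_gram_positive fraction of prey that are gram-positive
#'   (never preyed upon).
#' @param interaction_density mean probability that a given (predator,
#'   gram-negative prey) pair interacts.
#' @param ktw_exponent Kill-the-Winner targeting exponent: a prey's chance
#'   of being attacked scales with its niche size to this power (0 =
#'   uniform), concentrating predation on abundant prey as frequency-
#'   dependent selection predicts.
#' @param partition_strength niche-partitioning strength: every time a prey
#'   is claimed by a predator its weight for further predators is scaled by
#'   exp(-partition_strength), so predators largely hunt different prey (0 =
#'   independent draws).
#' @param attack_rate range (2-vector) of predation coefficients, in
#'   per-unit-predator-abundance per day. Each predator's first-claimed
#'   (primary) prey takes a coefficient near the top of the range; further
#'   prey take weak coefficients near the bottom, giving the prey-preference
#'   hierarchy seen in host-range assays.
#' @param prey_growth range of prey intrinsic growth rates r (per day).
#' @param carrying_capacity total prey carrying capacity K (abundance
#'   units; relative scale, default 1).
#' @param prey_capacity_sigma log-normal sd of per-prey carrying
#'   capacities (niche sizes); ~1 gives the long-tailed species-abundance
#'   distribution typical of 16S surveys.
#' @param decay_rate range of predator decay rates d (per day, > 0).
#' @param conversion conversion efficiency c of consumed prey into predator
#'   growth.
#' @param seasonal_amplitude range of the seasonal forcing amplitude on
#'   predator growth (per day).
#' @param seasonal_phase_jitter sd (days) of each predator's seasonal phase
#'   around the temperature peak: predators are temperature-linked on
#'   average but peak at individual times of year, so the predator guild
#'   does not move as one block.
#' @param fast_amplitude range of the amplitude of each of the two
#'   sub-annual forcing components every predator carries (per day).
#' @param fast_period range (days) of the sub-annual periods, drawn per
#'   predator and component: predator OTUs oscillate at frequencies from
#'   weeks to season, and the individual two-tone rhythms keep predators
#'   from moving in lockstep.
#' @param prey_seasonal_amplitude range of seasonal modulation of prey
#'   growth rates (relative, 0-1 scale).
#' @param observation_days integer days (0 = series start) at which the
#'   community is observed.
#' @param read_depth reads per sample for the general 16S pool.
#' @param predator_read_depth reads per sample for each dedicated predator
#'   amplicon pool.
#' @param process_noise_sd daily log-scale process noise sd on prey.
#' @param predator_noise_sd daily log-scale process noise sd on predators
#'   (demographic and micro-environmental variability of small
#'   populations; larger than the prey noise).
#' @param extinction_floor abundances below this (x K) are treated as
#'   extinct-but-detectable-later; prevents log-domain blowups.
#' @param n_sites number of sites (independent parameter draws each).
#' @param prey_overlap_fraction fraction of prey OTUs present in both the
#'   floc and liquor compartments; the rest split between them. Predators
#'   live in both.
#' @param predator_initial total initial predator abundance (x K).
#' @param temperature_mean,temperature_amplitude,temperature_phase yearly
#'   temperature sinusoid (deg C; phase in days).
#' @param burn_in days simulated before the observation window.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_prey = 200,
                       n_predators_bd = 10,
                       n_predators_bx = 10,
                       fraction_gram_positive = 0.25,
                       interaction_density = 0.04,
                       ktw_exponent = 0.6,
                       partition_strength = 2,
                       attack_rate = c(8000, 14000),
                       prey_growth = c(1.2, 1.8),
                       carrying_capacity = 1,
                       prey_capacity_sigma = 1.5,
                       decay_rate = c(0.04, 0.08),
                       conversion = 0.00128,
                       seasonal_amplitude = c(0.01, 0.025),
                       seasonal_phase_jitter = 60,
                       fast_amplitude = c(0.025, 0.05),
                       fast_period = c(40, 200),
                       prey_seasonal_amplitude = c(0, 0.3),
                       observation_days = study_days(),
                       read_depth = 5000,
                       predator_read_depth = 20000,
                       process_noise_sd = 0.003,
                       predator_noise_sd = 0.06,
                       extinction_floor = 1e-9,
                       n_sites = 1,
                       prey_overlap_fraction = 0.15,
                       predator_initial = 0.003,
                       temperature_mean = 20,
                       temperature_amplitude = 6,
                       temperature_phase = 64,
                       burn_in = 120) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_prey > 0, cfg$n_predators_bd >= 0, cfg$n_predators_bx >= 0,
            cfg$fraction_gram_positive >= 0, cfg$fraction_gram_positive <= 1,
            all(cfg$decay_rate > 0), cfg$carrying_capacity > 0,
            all(is.finite(unlist(cfg[sapply(cfg, is.numeric)]))))
  class(cfg) <- "sim_config"
  cfg
}

#' The study's 18-point yearly sampling calendar
#'
#' Monthly samples over one year plus four consecutive weekly samples in
#' late summer and in late winter (the monthly visit opening each weekly
#' run), as integer days since the series start.
#'
#' @return sorted integer vector of length 18.
#' @export
study_days <- function() {
  monthly <- 30 * (0:11)
  sort(unique(c(monthly, 150 + 7 * (1:3), 330 + 7 * (1:3))))
}

#' Pre-set simulation designs
#'
#' `"desk"` is a small configuration (200 prey, 10 + 10 predators, read
#' depth 5,000, 18 time points, one site) that simulates and samples in
#' seconds; `"full"` mirrors the study's dimensions (3 sites, ~3,600 prey
#' OTUs, ~100 bd and ~70 bx predators, ~35,000 reads per sample).
#'
#' @param scale `"desk"` or `"full"`.
#' @return a `sim_config`.
#' @export
default_study_design <- function(scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (scale == "desk") {
    sim_config()
  } else {
    sim_config(n_prey = 3600, n_predators_bd = 100, n_predators_bx = 70,
               read_depth = 35000, predator_read_depth = 30000, n_sites = 3)
  }
}

#' Seasonal temperature series
#'
#' A sinusoid with a one-year period: `mean + amplitude *
#' sin(2 pi (t - phase) / 365)`.
#'
#' @param times numeric days.
#' @param mean,amplitude,phase sinusoid parameters (`amplitude >= 0`,
#'   `phase` in days).
#' @return numeric series, one value per time.
#' @export
seasonal_temperature <- function(times, mean = 20, amplitude = 6, phase = 64) {
  if (amplitude < 0) abort("amplitude must be non-negative")
  mean + amplitude * sin(2 * pi * (times - phase) / 365)
}

#' Simulate latent community dynamics
#'
#' Runs the stochastic Ricker-type generalized Lotka-Volterra model of
#' [sim_config()] for every site and fraction compartment and returns the
#' latent trajectories at the observation times together with the true
#' predation adjacency. Per compartment, with daily steps:
#' \deqn{x_i(t+1) = x_i(t) \exp(r_i(t)(1 - X/K) - \sum_j a_{ij} y_j(t) + \epsilon)}
#' \deqn{y_j(t+1) = y_j(t) \exp(-d_j + c \sum_i a_{ij} x_i(t) + F_j(t) + \epsilon)}
#' where the prey forcing follows the temperature anomaly and F_j is the
#' predator's individual forcing: an annual component peaking at its own
#' phase (jittered around the temperature peak) plus a sub-annual
#' component with its own period and phase. The floc and liquor
#' compartments of a site share all predators but only
#' `prey_overlap_fraction` of prey.
#'
#' @param config a `sim_config`.
#' @param seed integer seed; the run is deterministic given (config, seed).
#' @return a `ground_truth` object: `adjacency` (tibble `predator_otu`,
#'   `prey_otu`, `coefficient`, `site`), `otus` (guilds and gram status),
#'   `taxonomy`, `compartments` (per site x fraction: latent relative
#'   abundance matrices at observation times, dates, temperature), and the
#'   `config` and `seed` used.
#' @export
simulate_dynamics <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_dynamics_impl(config, seed))
}

simulate_dynamics_impl <- function(cfg, seed) {
  n_bd <- cfg$n_predators_bd
  n_bx <- cfg$n_predators_bx
  n_pred <- n_bd + n_bx
  obs <- sort(cfg$observation_days)
  temp_obs <- seasonal_temperature(obs, cfg$temperature_mean,
                                   cfg$temperature_amplitude, cfg$temperature_phase)
  dates <- as.Date("2013-03-01") + obs
  sites <- paste0("S", seq_len(cfg$n_sites))
  all_adj <- list()
  all_otus <- list()
  compartments <- list()
  for (site in sites) {
    ids_prey <- sprintf("%s_prey%04d", site, seq_len(cfg$n_prey))
    ids_bd <- sprintf("%s_bd%03d", site, seq_len(n_bd))
    ids_bx <- sprintf("%s_bx%03d", site, seq_len(n_bx))
    ids_pred <- c(ids_bd, ids_bx)
    gram_pos <- stats::runif(cfg$n_prey) < cfg$fraction_gram_positive
    # per-prey niche sizes (log-normal species-abundance distribution)
    Ki_raw <- exp(stats::rnorm(cfg$n_prey, 0, cfg$prey_capacity_sigma))
    # predation matrix: predators x prey, gram-positive columns zero.
    # Each predator claims a prey range by weighted sampling: weights rise
    # with niche size (Kill-the-Winner targeting) and fall each time a prey
    # is claimed (niche partitioning: predators largely hunt different prey)
    A <- matrix(0, n_pred, cfg$n_prey, dimnames = list(ids_pred, ids_prey))
    gn <- which(!gram_pos)
    w0 <- (Ki_raw[gn] / exp(mean(log(Ki_raw[gn]))))^cfg$ktw_exponent
    claimed <- integer(length(gn))
    mean_range <- cfg$interaction_density * length(gn)
    for (j in if (n_pred > 0 && mean_range > 0) sample.int(n_pred) else integer(0)) {
      n_j <- min(max(1, stats::rpois(1, mean_range)), length(gn))
      w <- w0 * exp(-cfg$partition_strength * claimed)
      pick <- sample(seq_along(gn), n_j, prob = w)
      claimed[pick] <- claimed[pick] + 1L
      a_j <- c(stats::runif(1, cfg$attack_rate[1], cfg$attack_rate[2]),
               stats::runif(n_j - 1, 0.2, 0.7) * cfg$attack_rate[1])
      A[j, gn[pick]] <- a_j
    }
    # compartment membership of prey: shared / floc-only / liquor-only
    n_shared <- round(cfg$prey_overlap_fraction * cfg$n_prey)
    grp <- sample(rep(c("both", "floc", "liquor"),
                      c(n_shared, ceiling((cfg$n_prey - n_shared) / 2),
                        floor((cfg$n_prey - n_shared) / 2))))
    r <- stats::runif(cfg$n_prey, cfg$prey_growth[1], cfg$prey_growth[2])
    prey_seas <- stats::runif(cfg$n_prey, cfg$prey_seasonal_amplitude[1],
                              cfg$prey_seasonal_amplitude[2]) *
      sample(c(-1, 1), cfg$n_prey, replace = TRUE)
    d <- stats::runif(n_pred, cfg$decay_rate[1], cfg$decay_rate[2])
    s <- stats::runif(n_pred, cfg$seasonal_amplitude[1], cfg$seasonal_amplitude[2])
    phi <- cfg$temperature_phase + stats::rnorm(n_pred, 0, cfg$seasonal_phase_jitter)
    s_fast <- matrix(stats::runif(2 * n_pred, cfg$fast_amplitude[1],
                                  cfg$fast_amplitude[2]), n_pred)
    period_fast <- matrix(stats::runif(2 * n_pred, cfg$fast_period[1],
                                       cfg$fast_period[2]), n_pred)
    psi <- matrix(stats::runif(2 * n_pred, 0, cfg$fast_period[2]), n_pred)
    for (frac in c("floc", "liquor")) {
      in_comp <- grp %in% c("both", frac)
      forcing <- function(t) {
        s * sin(2 * pi * (t - phi) / 365) +
          s_fast[, 1] * sin(2 * pi * (t - psi[, 1]) / period_fast[, 1]) +
          s_fast[, 2] * sin(2 * pi * (t - psi[, 2]) / period_fast[, 2])
      }
      traj <- run_compartment(cfg, A[, in_comp, drop = FALSE], r[in_comp],
                              prey_seas[in_comp], d, forcing, obs,
                              Ki_raw[in_comp])
      colnames(traj) <- c(ids_prey[in_comp], ids_pred)
      compartments[[paste(site, frac, sep = ".")]] <- list(
        site = site, fraction = frac, days = obs, dates = dates,
        temperature = temp_obs, latent = traj
      )
    }
    nz <- which(A > 0, arr.ind = TRUE)
    all_adj[[site]] <- tibble(
      predator_otu = ids_pred[nz[, 1]], prey_otu = ids_prey[nz[, 2]],
      coefficient = A[nz], site = site
    )
    all_otus[[site]] <- tibble(
      otu_id = c(ids_prey, ids_bd, ids_bx),
      guild = rep(c("prey_candidate", "predator_bd", "predator_bx"),
                  c(cfg$n_prey, n_bd, n_bx)),
      gram_positive = c(gram_pos, rep(FALSE, n_pred)),
      site = site
    )
  }
  otus <- bind_rows(all_otus)
  structure(list(
    adjacency = bind_rows(all_adj) %>% arrange(.data$predator_otu, .data$prey_otu),
    otus = otus,
    taxonomy = synthetic_taxonomy(otus),
    compartments = compartments,
    config = cfg,
    seed = seed
  ), class = "ground_truth")
}

# daily-step Ricker gLV for one compartment; returns obs-times x OTUs matrix
# of relative abundances (prey columns first, then predators).
# Each prey OTU holds its own niche (carrying capacity K_i summing to ~K):
# without per-prey self-limitation, unpredated competitors pin the community
# total at K and predator equilibria collapse to zero.
run_compartment <- function(cfg, A, r, prey_seas, d, forcing, obs, Ki_raw) {
  n_prey <- length(r)
  n_pred <- length(d)
  K <- cfg$carrying_capacity
  floor_ab <- cfg$extinction_floor * K
  Ki <- Ki_raw / sum(Ki_raw) * K
  x <- Ki
  y <- rep(cfg$predator_initial * K / max(n_pred, 1), n_pred)
  days <- seq(-cfg$burn_in, max(obs))
  out <- matrix(NA_real_, length(obs), n_prey + n_pred)
  sig <- cfg$process_noise_sd
  for (t in days) {
    anomaly <- sin(2 * pi * (t - cfg$temperature_phase) / 365)
    predation <- if (n_pred > 0) drop(crossprod(A, y)) else 0  # per-prey pressure
    intake <- if (n_prey > 0) drop(A %*% x) else numeric(0)    # per-predator intake
    gx <- r * (1 + prey_seas * anomaly) * (1 - x / Ki) - predation +
      stats::rnorm(n_prey, 0, sig)
    gy <- -d + cfg$conversion * intake + forcing(t) +
      stats::rnorm(n_pred, 0, cfg$predator_noise_sd)
    x <- pmax(x * exp(pmin(gx, 2)), floor_ab)
    y <- pmax(y * exp(pmin(gy, 2)), floor_ab)
    if (any(!is.finite(c(x, y))) || sum(c(x, y)) > 1e6 * K) {
      abort(sprintf("dynamics diverged (day %d): check attack_rate/conversion", t))
    }
    hit <- match(t, obs)
    if (!is.na(hit)) out[hit, ] <- c(x, y) / sum(c(x, y))
  }
  out
}

# SILVA-style lineage strings for simulated OTUs; gram-positive prey are
# split between the two gram-positive phyla
synthetic_taxonomy <- function(otus) {
  lineage <- character(nrow(otus))
  gp_phyla <- rep(c("Firmicutes", "Actinobacteria"), length.out = sum(otus$gram_positive))
  lineage[otus$gram_positive] <- paste0("Bacteria;", gp_phyla,
                                        ";unclassified;unclassified;unclassified;unclassified")
  gn_prey <- !otus$gram_positive & otus$guild == "prey_candidate"
  gn_phyla <- rep(c("Proteobacteria", "Bacteroidetes"), length.out = sum(gn_prey))
  lineage[gn_prey] <- paste0("Bacteria;", gn_phyla,
                             ";unclassified;unclassified;unclassified;unclassified")
  lineage[otus$guild == "predator_bd"] <-
    "Bacteria;Proteobacteria;Deltaproteobacteria;Bdellovibrionales;Bdellovibrionaceae;Bdellovibrio"
  lineage[otus$guild == "predator_bx"] <-
    "Bacteria;Proteobacteria;Deltaproteobacteria;Bacteriovoracales;Bacteriovoracaceae;Bacteriovorax"
  parse_taxonomy(lineage, otus$otu_id)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Simulated community ground truth\n")
  cat("  compartments:", length(x$compartments),
      " OTUs/site:", x$config$n_prey + x$config$n_predators_bd + x$config$n_predators_bx, "\n")
  cat("  true predation edges:", nrow(x$adjacency), "\n")
  invisible(x)
}

#' Multinomial read sampling of a simulated community
#'
#' Draws `depth` sequencing reads per sample, per compartment, with
#' probabilities proportional to the latent abundances of all OTUs present
#' (predators included) — the compositional observation process of amplicon
#' sequencing.
#'
#' @param truth a `ground_truth` from [simulate_dynamics()].
#' @param depth reads per sample (default: the config's `read_depth`).
#' @param seed integer seed.
#' @return an `otu_tbl` in raw-counts mode covering all sites and
#'   fractions, with metadata (site, fraction, date, temperature) and the
#'   synthetic taxonomy attached.
#' @export
sample_reads <- function(truth, depth = truth$config$read_depth, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), depth > 0)
  with_seed(seed, {
    tabs <- lapply(truth$compartments, function(cmp) {
      draw_pool(cmp, colnames(cmp$latent), depth, truth)
    })
    combined <- bind_rows(lapply(tabs, as_tibble))
    new_otu_tbl(combined, mode = "raw_counts", taxonomy = truth$taxonomy)
  })
}

#' Sample the three sequencing pools of the study design
#'
#' The study sequenced three datasets from the same samples: a general 16S
#' pool plus dedicated amplicon pools for each predator clade, so predator
#' series have full within-clade depth. Returns the general pool and
#' clade-restricted pools as separate tables.
#'
#' @param truth a `ground_truth`.
#' @param depth general-pool reads per sample.
#' @param predator_depth reads per sample of each clade pool.
#' @param seed integer seed.
#' @return named list of `otu_tbl`s: `total`, `bd`, `bx`.
#' @export
sample_study_reads <- function(truth, depth = truth$config$read_depth,
                               predator_depth = truth$config$predator_read_depth,
                               seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), depth > 0, predator_depth > 0)
  guild_of <- setNames(truth$otus$guild, truth$otus$otu_id)
  with_seed(seed, {
    pools <- list(
      total = function(ids) ids,
      bd = function(ids) ids[guild_of[ids] == "predator_bd"],
      bx = function(ids) ids[guild_of[ids] == "predator_bx"]
    )
    out <- lapply(names(pools), function(pool) {
      dep <- if (pool == "total") depth else predator_depth
      tabs <- lapply(truth$compartments, function(cmp) {
        ids <- pools[[pool]](colnames(cmp$latent))
        draw_pool(cmp, ids, dep, truth)
      })
      new_otu_tbl(bind_rows(lapply(tabs, as_tibble)), mode = "raw_counts",
                  taxonomy = truth$taxonomy)
    })
    setNames(out, names(pools))
  })
}

# multinomial draws for one compartment restricted to `ids`
draw_pool <- function(cmp, ids, depth, truth) {
  lat <- cmp$latent[, ids, drop = FALSE]
  if (any(rowSums(lat) <= 0)) abort("all-zero latent sample: cannot draw reads")
  counts <- t(apply(lat, 1, function(p) rmultinom(1, depth, p)[, 1]))
  colnames(counts) <- ids
  sample_ids <- sprintf("%s_%s_t%02d", cmp$site, cmp$fraction, seq_along(cmp$days))
  rownames(counts) <- sample_ids
  guild_of <- setNames(truth$otus$guild, truth$otus$otu_id)
  meta <- tibble(sample_id = sample_ids, site = cmp$site, fraction = cmp$fraction,
                 date = cmp$dates, temperature = cmp$temperature)
  otu_table(counts, meta, guilds = guild_of[ids], taxonomy = truth$taxonomy,
            mode = "raw_counts")
}

#' Write a simulated data set to TSV files
#'
#' Counts, taxonomy, metadata and the true predation adjacency, in the same
#' formats [read_otu_table()] consumes.
#'
#' @param truth a `ground_truth`.
#' @param table an `otu_tbl` sampled from it.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_otu_table(table,
                  counts_path = file.path(dir, "counts.tsv"),
                  taxonomy_path = file.path(dir, "taxonomy.tsv"),
                  metadata_path = file.path(dir, "metadata.tsv"))
  readr::write_tsv(truth$adjacency, file.path(dir, "truth_adjacency.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Latent community tables of a simulated compartment
#'
#' Builds relative-mode predator and prey tables directly from the latent
#' compositions of one site-fraction compartment — the noise-free
#' observation limit of the community (what sequencing would measure at
#' unbounded depth). Prey tables exclude gram-positive OTUs; predator
#' abundances are renormalized within the predator guilds, mirroring the
#' dedicated predator amplicon pools.
#'
#' @param truth a `ground_truth` from [simulate_dynamics()].
#' @param compartment compartment name (e.g. `"S1.floc"`); defaults to the
#'   first.
#' @return named list of relative-mode `otu_tbl`s: `predators`, `prey`.
#' @export
latent_tables <- function(truth, compartment = names(truth$compartments)[1]) {
  stopifnot(inherits(truth, "ground_truth"))
  cmp <- truth$compartments[[compartment]]
  if (is.null(cmp)) abort(paste0("no compartment called ", compartment))
  lat <- cmp$latent
  guild_of <- setNames(truth$otus$guild, truth$otus$otu_id)
  gram_pos <- setNames(truth$otus$gram_positive, truth$otus$otu_id)
  meta <- tibble(
    sample_id = sprintf("%s_%s_t%02d", cmp$site, cmp$fraction, seq_along(cmp$days)),
    site = cmp$site, fraction = cmp$fraction, date = cmp$dates,
    temperature = cmp$temperature
  )
  rownames(lat) <- meta$sample_id
  prey_ids <- colnames(lat)[guild_of[colnames(lat)] == "prey_candidate" &
                              !gram_pos[colnames(lat)]]
  pred_ids <- colnames(lat)[guild_of[colnames(lat)] != "prey_candidate"]
  pred_m <- lat[, pred_ids, drop = FALSE]
  pred_m <- pred_m / rowSums(pred_m)
  list(
    predators = otu_table(pred_m, meta, guilds = guild_of[pred_ids],
                          taxonomy = truth$taxonomy, mode = "relative"),
    prey = otu_table(lat[, prey_ids, drop = FALSE], meta,
                     guilds = guild_of[prey_ids],
                     taxonomy = truth$taxonomy, mode = "relative")
  )
}
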