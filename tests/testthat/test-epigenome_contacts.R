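test_that("synthetic epigenomes have the requested block structure", {
  one <- synthetic_epigenome(100, state_freqs = c(active = 1, black = 0),
                             seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$state, "active")
  # geometric block lengths: empirical mean within 10% of the target
  ann <- synthetic_epigenome(1e4, mean_domain_len = 10, seed = 2)
  lens <- (ann$end - ann$start) / attr(ann, "nu")
  # drop the truncated last block
  expect_equal(mean(lens[-length(lens)]), 10, tolerance = 0.1)
  # no two consecutive blocks share a state
  expect_true(all(ann$state[-1] != ann$state[-nrow(ann)]))
  # near-uniform frequencies are recovered at large n
  freqs <- c(active = 0.25, HP1 = 0.25, PcG = 0.25, black = 0.25)
  big <- synthetic_epigenome(1e5, state_freqs = freqs, seed = 3)
  emp <- table(attr(big, "monomer_states")) / 1e5
  expect_true(all(abs(emp[names(freqs)] - freqs) < 0.02))
  expect_error(synthetic_epigenome(10, state_freqs = c(a = 0.5, b = 0.6)),
               "sum to 1")
})

test_that("annotations round-trip through BED and majority assignment", {
  ann <- synthetic_epigenome(500, mean_domain_len = 7, seed = 4, nu = 10000)
  f <- tempfile(fileext = ".bed")
  write_epigenome_bed(ann, f)
  states <- load_epigenome(f, region = c(0, 500 * 10000), nu = 10000)
  expect_equal(states, attr(ann, "monomer_states"))
  unlink(f)
})

test_that("majority-overlap assignment follows the stated rules", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr2L\t0\t6000\tYELLOW",
               "chr2L\t6000\t20000\tBLUE"), f)
  # monomer 1 is 60/40 YELLOW/BLUE -> active; monomer 2 fully BLUE -> PcG
  st <- load_epigenome(f, region = c(0, 20000), nu = 10000)
  expect_equal(st, c("active", "PcG"))
  # single covering interval gives a uniform vector
  writeLines("chr2L\t0\t50000\tGREEN", f)
  expect_equal(load_epigenome(f, region = c(0, 50000), nu = 10000),
               rep("HP1", 5))
  # uncovered monomers fall back to black with a warning
  writeLines("chr2L\t0\t10000\tRED", f)
  expect_warning(st3 <- load_epigenome(f, region = c(0, 30000), nu = 10000),
                 "uncovered")
  expect_equal(st3, c("active", "black", "black"))
  # unknown labels are an error
  writeLines("chr2L\t0\t10000\tPURPLE", f)
  expect_error(load_epigenome(f, region = c(0, 10000), nu = 10000), "unknown")
  unlink(f)
})

test_that("contact maps of a frozen straight chain are banded and linear in windows", {
  lat <- fcc_lattice(10, b = 1)
  conf <- straight_conf(16, lat)
  tr <- fake_traj(array(conf$pos, dim = c(16, 3, 4)), lat)
  map <- contact_map(tr, dc = 2.5 * lat$b)
  # contacts exactly for |i - j| <= 2 (distances b, 2b along the line);
  # at one monomer per bin the main diagonal holds no pairs
  doff <- abs(row(map$freq) - col(map$freq))
  expect_true(all(map$freq[doff >= 1 & doff <= 2] == 1))
  expect_true(all(map$freq[abs(row(map$freq) - col(map$freq)) > 2] == 0))
  expect_true(isSymmetric(map$counts))
  # window linearity: union counts = sum of disjoint windows
  tr$mcs <- c(0, 10, 20, 30)
  m1 <- contact_map(tr, window = c(0, 10), dc = 2.5)
  m2 <- contact_map(tr, window = c(20, 30), dc = 2.5)
  mu <- contact_map(tr, window = c(0, 30), dc = 2.5)
  expect_equal(mu$counts, m1$counts + m2$counts)
  expect_equal(mu$freq, (m1$freq * m1$n_frames + m2$freq * m2$n_frames) /
                 (m1$n_frames + m2$n_frames))
})

test_that("state-split contact probabilities obey the counting identity", {
  lat <- fcc_lattice(6, b = 1)
  states <- rep(c("active", "black"), each = 24)
  conf <- init_conformation("hedgehog", 48, lat, seed = 5, states = states)
  tr <- kmc_run(conf, energy_model(kappa = 0), kmc_config(1000, 100, 3))
  ps <- pc_by_state(tr)
  # pair-weighted average of intra and inter reproduces pc exactly
  lhs <- ifelse(ps$n > 0,
                (ifelse(ps$n_intra > 0, ps$p_intra, 0) * ps$n_intra +
                 ifelse(ps$n_inter > 0, ps$p_inter, 0) * ps$n_inter) / ps$n,
                NA)
  expect_equal(lhs, ps$pc, tolerance = 1e-12)
  # single-state chain: p_intra == pc, no inter pairs
  conf1 <- init_conformation("hedgehog", 30, lat, seed = 6,
                             states = rep("black", 30))
  tr1 <- kmc_run(conf1, energy_model(kappa = 0), kmc_config(500, 100, 4))
  ps1 <- pc_by_state(tr1)
  expect_equal(ps1$p_intra, ps1$pc)
  expect_true(all(ps1$n_inter == 0))
})

test_that("same-state attraction enriches intra-state contacts in a toy copolymer", {
  lat <- fcc_lattice(4, b = 1)   # 256 sites, N = 128 -> Phi = 0.5
  states <- rep(rep(c("active", "black"), each = 16), 4)
  gen <- function(seed) init_conformation("hedgehog", 128, lat, seed = seed,
                                          states = states)
  cfg <- kmc_config(2e4, snapshot_every = 500, seed = 11)
  run_at <- function(E_i) {
    model <- if (E_i == 0) energy_model(kappa = 0)
             else energy_model(kappa = 0, E_i = E_i)
    run_replicas(gen, model, cfg, 2)
  }
  t_null <- run_at(0)
  t_att <- run_at(-1)
  win <- c(1e4, 2e4)
  ps_null <- pc_by_state(t_null, window = win)
  ps_att <- pc_by_state(t_att, window = win)
  mid <- ps_att$s >= 4 & ps_att$s <= 40
  # intra enriched, inter depleted relative to the sequence average
  expect_gt(mean(ps_att$p_intra[mid] / ps_att$pc[mid], na.rm = TRUE), 1)
  expect_lt(mean(ps_att$p_inter[mid] / ps_att$pc[mid], na.rm = TRUE), 1)
  # and the enrichment exceeds the null model's
  expect_gt(mean(ps_att$p_intra[mid] / ps_att$pc[mid], na.rm = TRUE),
            mean(ps_null$p_intra[mid] / ps_null$pc[mid], na.rm = TRUE))
  # block-diagonal enrichment of the contact map versus the null
  bmap_att <- contact_map(t_att, window = win, bin = 16)
  bmap_null <- contact_map(t_null, window = win, bin = 16)
  same_block <- outer(rep(c(1, 2), each = 1, times = 4),
                      rep(c(1, 2), each = 1, times = 4), "==")
  off <- upper.tri(bmap_att$freq)
  enrich <- function(m) mean(m$freq[off & same_block]) /
    mean(m$freq[off & !same_block])
  expect_gt(enrich(bmap_att), enrich(bmap_null))
})

test_that("ratio time courses are flat at unit ratio without state coupling", {
  lat <- fcc_lattice(4, b = 1)   # denser box so long-range contacts occur
  states <- rep(c("active", "HP1", "PcG", "black"), each = 16)
  gen <- function(seed) init_conformation("hedgehog", 64, lat, seed = seed,
                                          states = states)
  trajs <- run_replicas(gen, energy_model(kappa = 0),
                        kmc_config(4000, 100, 7), 6)
  rt <- ratio_timecourse(trajs, bands = rbind(c(1, 8), c(9, 40)))
  expect_true(all(is.finite(rt$ratio_intra)))
  expect_equal(mean(rt$ratio_intra), 1, tolerance = 0.1)
  expect_equal(mean(rt$ratio_inter), 1, tolerance = 0.1)
  # single-state chain: intra ratio identically 1
  gen1 <- function(seed) init_conformation("hedgehog", 64, lat, seed = seed,
                                           states = rep("black", 64))
  tr1 <- run_replicas(gen1, energy_model(kappa = 0), kmc_config(500, 100, 2), 1)
  rt1 <- ratio_timecourse(tr1, bands = rbind(c(1, 16)))
  expect_true(all(abs(rt1$ratio_intra - 1) < 1e-12))
})

test_that("pair kinetics decompose a telegraph signal exactly", {
  dt <- 2
  # constructed run pattern: 3 above, 4 below, 5 above, 2 below, 3 above
  d <- rep(c(10, 1, 10, 1, 10), times = c(3, 4, 5, 2, 3))
  series <- data.frame(time = seq_along(d) * dt - dt, distance = d)
  k <- pair_kinetics(series, threshold = 5)
  expect_false(k$censored)
  expect_equal(k$tau_first, 3 * dt)
  expect_equal(k$tau_c, c(4, 2) * dt)
  expect_equal(k$tau_s, 5 * dt)
  expect_equal(k$trailing, 3 * dt)
  expect_equal(k$tau_first + sum(k$tau_c) + sum(k$tau_s) + k$trailing,
               k$span)
  # always below: tau_first 0, one full-span contact, no searches
  s_low <- data.frame(time = 0:9, distance = rep(0.1, 10))
  k_low <- pair_kinetics(s_low, threshold = 5)
  expect_equal(k_low$tau_first, 0)
  expect_equal(k_low$tau_c, k_low$span)
  expect_length(k_low$tau_s, 0)
  # never below: censored at the span
  s_high <- data.frame(time = 0:9, distance = rep(10, 10))
  k_high <- pair_kinetics(s_high, threshold = 5)
  expect_true(k_high$censored)
  expect_equal(k_high$tau_first, k_high$span)
  expect_length(k_high$tau_c, 0)
})

test_that("kinetics duration identity holds on simulated distance series", {
  lat <- fcc_lattice(5, b = 1)
  conf <- init_conformation("hedgehog", 40, lat, seed = 8)
  trajs <- run_replicas(function(s) init_conformation("hedgehog", 40, lat,
                                                      seed = s),
                        energy_model(kappa = 0), kmc_config(2000, 10, 5), 3)
  ek <- ensemble_kinetics(trajs, 5, 35)
  expect_equal(ek$threshold, 2 * sqrt(2))
  expect_equal(ek$censored_fraction, mean(ek$censored))
  for (tr in trajs) {
    k <- pair_kinetics(pair_distance_series(tr, 5, 35), ek$threshold)
    expect_equal(k$tau_first + sum(k$tau_c) + sum(k$tau_s) + k$trailing,
                 k$span)
  }
})

test_that("map correlation behaves on identical, negated and noise maps", {
  set.seed(13)
  A <- matrix(stats::runif(400), 20)
  A <- (A + t(A)) / 2
  expect_equal(map_correlation(A, A), 1)
  expect_equal(map_correlation(A, -A), -1)
  B <- matrix(stats::runif(400), 20); B <- (B + t(B)) / 2
  n_entries <- sum(upper.tri(A) & (col(A) - row(A)) > 0)
  expect_lt(abs(map_correlation(A, B)), 3 / sqrt(n_entries))
  expect_error(map_correlation(A, matrix(0, 5, 5)), "different grids")
})

test_that("slowing down with stronger same-state attraction on a toy copolymer", {
  lat <- fcc_lattice(5, b = 1)    # 500 sites, N = 256 -> Phi ~ 0.5
  states <- rep(rep(chromatin_states(), each = 16), 4)
  gen <- function(seed) init_conformation("hedgehog", 256, lat, seed = seed,
                                          states = states)
  cfg <- kmc_config(5000, snapshot_every = 250, seed = 17)
  g1_at <- function(E_i) {
    model <- if (E_i == 0) energy_model(kappa = 0)
             else energy_model(kappa = 0, E_i = E_i)
    trajs <- run_replicas(gen, model, cfg, 3)
    msd_monomer(trajs, lags = 2500)$value
  }
  vals <- vapply(c(0, -0.5, -1), g1_at, numeric(1))
  expect_true(all(diff(vals) < 0))
})
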