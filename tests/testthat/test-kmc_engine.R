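test_that("total energy matches simple closed-form cases", {
  lat <- fcc_lattice(6, b = 1)
  conf <- straight_conf(8, lat)
  expect_equal(total_energy(conf, energy_model(kappa = 3.7)), 0)
  # 3 monomers with one 60-degree fcc turn: E = kappa (1 - 1/2)
  pos <- rbind(c(2L, 2L, 2L), c(3L, 3L, 2L), c(4L, 3L, 3L))
  stopifnot(sum(abs(pos[3, ] - pos[2, ])) == 2)
  turn <- conformation(pos, lat)
  expect_length(validate_conformation(turn), 0)
  cosang <- sum((pos[2, ] - pos[1, ]) * (pos[3, ] - pos[2, ])) / 2
  expect_equal(cosang, 0.5)
  expect_equal(total_energy(turn, energy_model(kappa = 2)), 1.0)
})

test_that("total energy equals the brute-force double-loop evaluator", {
  lat <- fcc_lattice(5, b = 1)
  states4 <- chromatin_states()
  set.seed(5)
  for (rep in 1:5) {
    conf <- init_conformation("random_collapse", 50, lat, seed = 100 + rep)
    conf$states <- sample(states4, 50, replace = TRUE)
    U <- matrix(0, 4, 4, dimnames = list(states4, states4))
    diag(U) <- c(-0.3, -0.5, -0.2, -0.8)
    U["active", "black"] <- U["black", "active"] <- 0.15
    model <- energy_model(kappa = 1.3, U = U)
    expect_equal(total_energy(conf, model),
                 reference_energy(conf, 1.3, U), tolerance = 1e-10)
  }
})

test_that("moves onto illegally occupied sites are rejected", {
  lat <- fcc_lattice(6, b = 1)
  conf <- straight_conf(8, lat)
  model <- energy_model(kappa = 0)
  # folding an end monomer onto its consecutive neighbour is legal stored
  # length; direction 1 is the (1,1,0) step
  res <- kmc_attempt_move(conf, model, monomer = 1, direction = 1)
  expect_true(res$legal)
  expect_true(res$accepted)   # dE <= 0 at kappa = 0: Metropolis accepts
  expect_length(validate_conformation(res$conformation), 0)
  # a bent chain whose tail monomer 4 sits one lattice step from monomer
  # 1's site: the proposal onto a site held by a non-consecutive monomer
  # must be rejected as illegal
  pos <- rbind(c(2L, 2L, 2L), c(3L, 3L, 2L), c(4L, 2L, 2L), c(3L, 2L, 1L))
  conf2 <- conformation(pos, lat)
  expect_length(validate_conformation(conf2), 0)
  # direction 7 is (-1, 0, 1): monomer 4 -> (2,2,2), occupied by monomer 1
  res2 <- kmc_attempt_move(conf2, model, monomer = 4, direction = 7)
  expect_false(res2$legal)
  expect_false(res2$accepted)
  expect_equal(res2$conformation$pos, pos)
})

test_that("dense runs with interactions keep every snapshot valid and audit energy", {
  # Phi = 1 box: N = 256 on S = 4 (256 sites), kappa > 0 and E_i < 0
  lat <- fcc_lattice(4, b = 1)
  conf <- init_conformation("hedgehog", 256, lat, seed = 9,
                            states = rep(chromatin_states(), each = 64))
  model <- energy_model(kappa = 1.2, E_i = -0.4)
  tr <- kmc_run(conf, model, kmc_config(400, snapshot_every = 40, seed = 4,
                                        energy_check_every = 50))
  expect_lt(tr$audit_max_error, 1e-6)
  for (k in seq_len(n_snapshots(tr))) {
    conf_k <- snapshot_conformation(tr, k)
    expect_length(validate_conformation(conf_k), 0)
  }
  # recomputed total energy of the last snapshot equals the logged value
  last <- snapshot_conformation(tr, n_snapshots(tr))
  expect_equal(total_energy(last, model), tr$energy[n_snapshots(tr)],
               tolerance = 1e-6)
})

test_that("runs are deterministic, and zero MCS returns the input state", {
  lat <- fcc_lattice(6, b = 1)
  conf <- init_conformation("hedgehog", 64, lat, seed = 2)
  model <- energy_model(kappa = 1)
  t0 <- kmc_run(conf, model, kmc_config(0, 10, 5))
  expect_equal(n_snapshots(t0), 1)
  expect_equal(t0$coords[, , 1], conf$pos + conf$img * lat$twoS)
  a <- kmc_run(conf, model, kmc_config(500, 50, 7))
  b <- kmc_run(conf, model, kmc_config(500, 50, 7))
  expect_identical(a$coords, b$coords)
  expect_identical(a$energy, b$energy)
  c2 <- kmc_run(conf, model, kmc_config(500, 50, 8))
  expect_false(identical(a$coords, c2$coords))
})

test_that("a single free monomer diffuses one squared bond length per MCS", {
  lat <- fcc_lattice(4, b = 2)
  conf <- conformation(matrix(c(4L, 4L, 4L), 1), lat)
  tr <- kmc_run(conf, energy_model(kappa = 0), kmc_config(4000, 1, 3))
  expect_equal(tr$acceptance_rate, 1)
  g1 <- msd_monomer(tr, lags = c(1, 2, 4, 8))
  # every MCS is one guaranteed b-step: lag-1 MSD is exactly b^2
  expect_equal(g1$value[1], lat$b^2)
  # random-walk linearity in the lag
  expect_equal(g1$value / g1$lag_mcs, rep(lat$b^2, 4), tolerance = 0.1)
})

test_that("uphill moves are suppressed at high rigidity (effective zero temperature)", {
  lat <- fcc_lattice(6, b = 1)
  conf <- init_conformation("random_collapse", 40, lat, seed = 6)
  model <- energy_model(kappa = 60)   # e^(-30) per half-unit: never accepted
  tr <- kmc_run(conf, model, kmc_config(2000, 20, 1))
  expect_true(all(diff(tr$energy) <= 1e-9))
})

test_that("detailed balance: toy-system energy levels follow Boltzmann weights", {
  # N = 3 on an S = 2 box; enumerate all valid configurations exhaustively
  lat <- fcc_lattice(2, b = 1)
  kap <- 1.3
  grid <- expand.grid(i = 0:3, j = 0:3, k = 0:3)
  grid <- as.matrix(grid[rowSums(grid) %% 2 == 0, ])
  # valid (p1, p2, p3) chains: bonds zero or NN (min image), occupancy legal
  bond_ok <- function(a, b) {
    d <- b - a; d <- d - 4 * round(d / 4)
    s <- sum(abs(d))
    s == 0 || (s == 2 && all(abs(d) <= 1))
  }
  bend_E <- function(p) {
    u <- p[2, ] - p[1, ]; u <- u - 4 * round(u / 4)
    v <- p[3, ] - p[2, ]; v <- v - 4 * round(v / 4)
    if (all(u == 0) || all(v == 0)) return(0)
    kap * (1 - sum(u * v) / 2)
  }
  energies <- c()
  for (i1 in 1:32) for (i2 in 1:32) for (i3 in 1:32) {
    p <- grid[c(i1, i2, i3), , drop = FALSE]
    if (!bond_ok(p[1, ], p[2, ]) || !bond_ok(p[2, ], p[3, ])) next
    # occupancy: only consecutive monomers may share a site
    if (i1 == i3 && i1 != i2) next
    if (i1 == i2 && i2 == i3) next
    energies <- c(energies, bend_E(p))
  }
  lev <- sort(unique(round(energies, 9)))
  g <- table(factor(round(energies, 9), levels = lev))
  p_theory <- as.numeric(g * exp(-lev)) / sum(g * exp(-lev))
  # simulate and classify snapshots by energy
  conf <- conformation(rbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(2L, 2L, 0L)), lat)
  tr <- kmc_run(conf, energy_model(kappa = kap),
                kmc_config(2e5, snapshot_every = 50, seed = 12))
  obs <- table(factor(round(tr$energy[-1], 9), levels = lev))
  expect_equal(sum(obs), n_snapshots(tr) - 1)  # no unexpected energy levels
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = p_theory))
  expect_gt(chi$p.value, 0.01)
})

test_that("dilute flexible chains equilibrate to the enumerated statistics", {
  # N = 2: excluded volume plays no role between bonded monomers, so the
  # equilibrium end-to-end distance is exactly the phantom value (12/13) b^2
  lat <- fcc_lattice(6, b = 1)
  tr2 <- run_replicas(function(seed) straight_conf(2, lat),
                      energy_model(kappa = 0), kmc_config(2e4, 20, 31), 4)
  R2_2 <- distance_moments(tr2, window = c(2e3, 2e4))
  expect_equal(R2_2$R2[R2_2$s == 1], phantom_end_to_end(2, 0, 1),
               tolerance = 0.03)

  # N = 4: enumerate every bond sequence of the actual self-avoiding
  # stored-length chain (13^3 states, uniform weights at kappa = 0) and
  # compare the simulated mean squared end-to-end distance with the exact
  # average
  off <- rbind(offsets12(), c(0, 0, 0))
  re2_sum <- 0; n_valid <- 0
  for (b1 in 1:13) for (b2 in 1:13) for (b3 in 1:13) {
    p1 <- c(0, 0, 0); p2 <- p1 + off[b1, ]; p3 <- p2 + off[b2, ]
    p4 <- p3 + off[b3, ]
    # occupancy: non-consecutive monomers may not coincide
    if (all(p1 == p3) || all(p2 == p4) || all(p1 == p4)) next
    re2_sum <- re2_sum + sum((p4 - p1)^2) / 2
    n_valid <- n_valid + 1
  }
  re2_exact <- re2_sum / n_valid
  tr4 <- run_replicas(function(seed) straight_conf(4, lat),
                      energy_model(kappa = 0), kmc_config(4e4, 20, 41), 4)
  R2_4 <- distance_moments(tr4, window = c(4e3, 4e4))
  expect_equal(R2_4$R2[R2_4$s == 3], re2_exact, tolerance = 0.03)

  # N = 8: excluded volume swells the chain relative to the phantom value;
  # the correction is positive and modest
  tr8 <- run_replicas(function(seed) straight_conf(8, lat),
                      energy_model(kappa = 0), kmc_config(2e4, 100, 21), 8)
  R2_8 <- distance_moments(tr8, window = c(5e3, 2e4))
  ratio <- R2_8$R2[R2_8$s == 7] / phantom_end_to_end(8, 0, 1)
  expect_gt(ratio, 1)
  expect_lt(ratio, 1.5)
})

test_that("replica ensembles are order-stable and share configuration", {
  lat <- fcc_lattice(5, b = 1)
  gen <- function(seed) init_conformation("hedgehog", 30, lat, seed = seed)
  model <- energy_model(kappa = 0.5)
  single <- kmc_run(gen(3), model, kmc_config(200, 20, 3))
  reps <- run_replicas(gen, model, kmc_config(200, 20, 3), 2)
  expect_identical(reps[[1]]$coords, single$coords)
  expect_false(identical(reps[[1]]$coords, reps[[2]]$coords))
  expect_equal(reps[[2]]$config$seed, 4L)
})
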