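test_that("nuclear density handles volume, diameter and bad input", {
  expect_equal(nuclear_density(6e9, nuclear_diameter = 9000), 0.015,
               tolerance = 0.05)
  expect_equal(nuclear_density(12.2e6, nuclear_volume = 2.6e9), 0.005,
               tolerance = 0.07)
  expect_error(nuclear_density(0, nuclear_volume = 1), "positive")
  expect_error(nuclear_density(1e6), "exactly one")
  expect_error(nuclear_density(1e6, nuclear_volume = 1, nuclear_diameter = 1),
               "exactly one")
})

test_that("entanglement report scales as rho^-2 from the calibrated anchor", {
  dros <- chromatin_preset("drosophila")
  # same fibre queried at the yeast density reproduces the yeast value
  ent_y <- entanglement(dros, chain_length = 750e3, rho = 0.005)
  expect_equal(ent_y$Ne / 1e3, 920, tolerance = 0.01)
  # drosophila 20 Mbp chromosome: L/Le ~ 70
  ent_d <- entanglement(dros, chain_length = 20e6)
  expect_equal(ent_d$ratio, 70.2, tolerance = 0.01)
  # exact rho^-2 scaling
  e1 <- entanglement(dros, 1e6, rho = 0.006)
  e2 <- entanglement(dros, 1e6, rho = 0.012)
  expect_equal(e1$Ne / e2$Ne, 4, tolerance = 1e-12)
  # chain_length = Ne gives ratio 1
  expect_equal(entanglement(dros, dros$Ne0)$ratio, 1)
  # uncalibrated preset falls back to the absolute relation with a warning
  cust <- chromatin_preset("custom", rho = 0.009)
  expect_warning(ent_c <- entanglement(cust, 1e6), "calibrated")
  expect_gt(ent_c$Ne, 0)
})

test_that("naive coarse-graining volume-fraction ratio follows n^1/2 (lk0/b0)^3/2", {
  expect_equal(naive_cg_phi_ratio(5, 5), 25)
  expect_equal(naive_cg_phi_ratio(1, 1), 1)
  expect_equal(naive_cg_phi_ratio(4, 1), 2)
})

test_that("cg geometry reproduces the published drosophila parameter rows", {
  dros <- chromatin_preset("drosophila")
  g10 <- solve_cg_geometry(dros, n = 50, phi = 0.97)
  expect_equal(g10$b, 115.3, tolerance = 0.015)
  expect_equal(g10$lk, 274, tolerance = 0.015)
  g2 <- solve_cg_geometry(dros, n = 10, phi = 0.049)
  expect_equal(g2$b, 24.9, tolerance = 0.015)
  expect_equal(g2$lk, 252, tolerance = 0.015)
})

test_that("cg geometry scales as phi^(1/3) in b and phi^(-2/3) in lk/b", {
  dros <- chromatin_preset("drosophila")
  f <- 1.7
  g1 <- solve_cg_geometry(dros, n = 25, phi = 0.4)
  g2 <- solve_cg_geometry(dros, n = 25, phi = 0.4 * f)
  expect_equal(g2$b / g1$b, f^(1 / 3), tolerance = 1e-12)
  expect_equal(g2$lk_b / g1$lk_b, f^(-2 / 3), tolerance = 1e-12)
})

test_that("rigidity-free special case of the solver matches the naive ratio", {
  # when lk = b (no added rigidity), volume conservation forces
  # Phi/Phi0 = sqrt(n) for a fibre with lk0 = b0
  p <- chromatin_preset("custom", rho = 0.006, nu0 = 200, b0 = 12, lk0 = 12,
                        Ne0 = 300e3)
  n <- 9
  b_naive <- sqrt(n * p$b0 * p$lk0)    # = b0 sqrt(n)
  rho_fs <- p$rho / p$nu0
  phi0 <- rho_fs * p$b0^3 / sqrt(2)
  phi_naive <- rho_fs * b_naive^3 / (sqrt(2) * n)
  expect_equal(phi_naive / phi0, naive_cg_phi_ratio(n, 1), tolerance = 1e-12)
  # and the solver inverts it: requesting that phi returns b_naive
  g <- solve_cg_geometry(p, n, phi_naive)
  expect_equal(g$b, b_naive, tolerance = 1e-12)
})

test_that("mean bond-angle cosine equals the 12-direction enumeration", {
  set.seed(7)
  kappas <- c(0, stats::runif(50, 0, 20))
  for (k in kappas)
    expect_equal(mean_cos_theta(k), enum_mean_cos(k), tolerance = 1e-12)
  expect_equal(mean_cos_theta(0), 0)
  expect_equal(mean_cos_theta(1e6), 1)
  expect_error(mean_cos_theta(-1), "non-negative")
})

test_that("Kuhn ratio is monotone in kappa, bounded in [1, 25)", {
  ks <- seq(0, 40, by = 0.25)
  r <- kuhn_ratio_from_kappa(ks)
  expect_true(all(diff(r) > 0))
  expect_equal(r[1], 1)
  expect_true(all(r >= 1 & r < 25))
  expect_equal(kuhn_ratio_from_kappa(1e8), 25, tolerance = 1e-9)
})

test_that("kappa_from_kuhn_ratio inverts the forward map", {
  expect_equal(kappa_from_kuhn_ratio(1), 0)
  expect_error(kappa_from_kuhn_ratio(25), "unreachable")
  expect_error(kappa_from_kuhn_ratio(0.5), "unreachable")
  targets <- c(1.01, 1.5, 2.379, 5, 10, 20, 24.5)
  for (tg in targets)
    expect_equal(kuhn_ratio_from_kappa(kappa_from_kuhn_ratio(tg)), tg,
                 tolerance = 1e-8)
})

test_that("phantom end-to-end distance matches limits and MC sampling", {
  expect_equal(phantom_end_to_end(1, 3, 2), 0)
  # kappa = 0: freely-jointed with stored length
  for (N in c(2, 10, 100))
    expect_equal(phantom_end_to_end(N, 0, 1.5), (12 / 13) * 1.5^2 * (N - 1))
  # large-N slope tends to (12/13) b^2 (1+x)/(1-x)
  x <- (12 / 13) * mean_cos_theta(2)
  slope <- (phantom_end_to_end(20001, 2) - phantom_end_to_end(20000, 2))
  expect_equal(slope, (12 / 13) * (1 + x) / (1 - x), tolerance = 1e-6)
  # sampling oracle at N = 100, kappa = 2
  mc <- phantom_chain_mc(100, 2, n_samples = 1e5)
  expect_lt(abs(phantom_end_to_end(100, 2) - mc$mean), 3 * mc$se)
})

test_that("cg table carries consistent records and inverts Nk targets", {
  dros <- chromatin_preset("drosophila")
  tab <- build_cg_table(dros, nu = c(2000, 10000), phi = c(0.049, 0.97))
  expect_equal(tab$Nk[2] / 1e3, 23.8, tolerance = 0.02)
  expect_equal(tab$Nk, tab$nu * tab$lk / tab$b, tolerance = 1e-12)
  expect_equal(kuhn_ratio_from_kappa(tab$kappa), tab$lk / tab$b,
               tolerance = 1e-8)
  # requesting Nk instead of phi round-trips
  tab2 <- build_cg_table(dros, nu = 10000, Nk = tab$Nk[2])
  expect_equal(tab2$phi, 0.97, tolerance = 1e-9)
  expect_equal(tab2$b, tab$b[2], tolerance = 1e-12)
  # reference-scale self-consistency: at nu = nu0 with phi chosen so that
  # lk = lk0, the solver returns a bond length close to b0 (the small
  # mismatch reflects the published fibre parameters themselves)
  phi_ref <- phi_from_kuhn_size(dros, 200, 1000)
  g <- solve_cg_geometry(dros, 1, phi_ref)
  expect_equal(g$lk_b, 5, tolerance = 1e-9)
  expect_equal(g$b, dros$b0, tolerance = 0.10)
  expect_error(solve_cg_geometry(dros, 5000, 0.049), "unreachable")
})
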