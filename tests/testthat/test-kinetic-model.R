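test_that("rate constant validation rejects non-positive or non-finite values", {
  expect_error(rate_constants(0, 1, 1, 1, 1, 1), "positive")
  expect_error(rate_constants(1, -2, 1, 1, 1, 1), "positive")
  expect_error(rate_constants(1, 1, Inf, 1, 1, 1), "positive")
  expect_error(simulate_network(example_rates(), a0 = -1e-3, l0 = 5e-4,
                                time_grid = 0:10), "positive")
  expect_error(simulate_network(example_rates(), time_grid = c(1, 2, 3)),
               "start at 0")
  expect_error(simulate_network(example_rates(), time_grid = c(0, 5, 5)),
               "strictly increasing")
})

test_that("symmetric branches give identical Z and E trajectories", {
  k <- rate_constants(k1 = 50, k_m1 = 0.01, k1Z = 0.015, k_m1Z = 0.003,
                      k1E = 0.015, k_m1E = 0.003)
  traj <- simulate_network(k, 1e-3, 5e-4, seq(0, 1000, by = 10))
  expect_lt(max(abs(traj$Z_M - traj$E_M)) / max(traj$Z_M), 1e-9)
})

test_that("swapping the Z and E branch constants swaps the trajectories", {
  k <- example_rates()
  ks <- rate_constants(k$k1, k$k_m1, k$k1E, k$k_m1E, k$k1Z, k$k_m1Z)
  grid <- seq(0, 2000, by = 20)
  a <- simulate_network(k, 1e-3, 5e-4, grid)
  b <- simulate_network(ks, 1e-3, 5e-4, grid)
  expect_equal(a$Z_M, b$E_M, tolerance = 1e-9)
  expect_equal(a$E_M, b$Z_M, tolerance = 1e-9)
  expect_equal(a$I_M, b$I_M, tolerance = 1e-9)
})

test_that("both mass totals are conserved along the trajectory", {
  traj <- simulate_network(example_rates(), 1e-3, 5e-4,
                           c(0, 10^seq(-3, 5, length.out = 100)))
  err <- conservation_error(traj)
  expect_lt(err[["amine"]], 1e-9)
  expect_lt(err[["aldehyde"]], 1e-9)
})

test_that("closed-form ratios match their algebraic identities", {
  k_eq <- rate_constants(1, 1, 1, 1, 1, 1)
  expect_equal(closed_form_ratios(k_eq), list(keq_ze = 1, initial_ratio = 1))
  k_prop <- rate_constants(10, 0.01, 0.04, 0.005, 0.02, 0.005)
  expect_equal(closed_form_ratios(k_prop),
               list(keq_ze = 2, initial_ratio = 2))
  expect_equal(closed_form_ratios(example_rates()),
               list(keq_ze = 4, initial_ratio = 2))
})

test_that("long- and short-time simulated Z/E match the closed forms for the reference set", {
  k <- example_rates()
  traj <- simulate_network(k, 1e-3, 5e-4,
                           c(0, 10^seq(-3, 5, length.out = 120)))
  ratio <- traj$Z_M / traj$E_M
  n <- nrow(traj)
  i0 <- which.min(abs(traj$t_min - 1e-3))
  expect_lt(rel_err(ratio[n], 4.0), 1e-4)
  expect_lt(rel_err(ratio[i0], 2.0), 1e-4)
})

test_that("regime classification follows the rho thresholds", {
  # k1 * a0 = 10 min^-1 against k1Z + k1E = 0.03 min^-1: rho ~ 333
  k_fast <- rate_constants(1e4, 2, 0.02, 0.002, 0.01, 0.004)
  expect_identical(classify_regime(k_fast, 1e-3), "fast_preequilibrium")
  # k1 * a0 = 0.001 min^-1 against k1Z + k1E = 0.1 min^-1: rho = 0.01
  k_slow <- rate_constants(1, 2, 0.06, 0.01, 0.04, 0.01)
  expect_identical(classify_regime(k_slow, 1e-3), "slow_bimolecular")
  k_mid <- rate_constants(30, 2, 0.02, 0.002, 0.01, 0.004)
  expect_identical(classify_regime(k_mid, 1e-3), "intermediate")
})

test_that("equilibrium and initial-flux oracles hold over sampled rate sets", {
  for (k in draw_raw_rates(25, seed = 11)) {
    cf <- closed_form_ratios(k)
    traj <- simulate_network(k, 1e-3, 5e-4, limits_grid(k))
    n <- nrow(traj)
    expect_lt(rel_err(traj$Z_M[n] / traj$E_M[n], cf$keq_ze), 1e-4)
    i0 <- 2L  # first positive time, 1e-3 of the fastest branch timescale
    expect_lt(rel_err(traj$Z_M[i0] / traj$E_M[i0], cf$initial_ratio), 1e-3)
  }
})

test_that("in the slow regime the ratio settles no later than either enamine curve", {
  ks <- sample_rate_constants("slow_bimolecular", 3, seed = 21)
  for (k in ks) {
    traj <- simulate_network(k, 1e-3, 5e-4, seq(0, 1800, by = 5))
    keq <- closed_form_ratios(k)$keq_ze
    ok <- traj$E_M > 0
    t_ratio <- time_to_asymptote(traj$t_min[ok], traj$Z_M[ok] / traj$E_M[ok],
                                 keq, frac = 0.1)
    t_z <- time_to_asymptote(traj$t_min, traj$Z_M,
                             traj$Z_M[nrow(traj)], frac = 0.1)
    t_e <- time_to_asymptote(traj$t_min, traj$E_M,
                             traj$E_M[nrow(traj)], frac = 0.1)
    expect_lte(t_ratio, t_z)
    expect_lte(t_ratio, t_e)
  }
})

test_that("trajectory export columns and initial state follow the contract", {
  traj <- simulate_network(example_rates(), 1e-3, 5e-4, seq(0, 100, 10))
  expect_named(as.data.frame(traj),
               c("t_min", "A_M", "L_M", "I_M", "Z_M", "E_M"))
  expect_identical(traj$t_min[1], 0)
  expect_identical(unname(unlist(traj[1, c("I_M", "Z_M", "E_M")])),
                   c(0, 0, 0))
  # explicit override of the initial state
  traj2 <- simulate_network(example_rates(), 1e-3, 5e-4, seq(0, 100, 10),
                            init = c(Z = 1e-4))
  expect_identical(traj2$Z_M[1], 1e-4)
})
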