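test_that("ratio construction guards the division and keeps the curve finite", {
  t <- seq(0, 90, by = 10)
  e <- c(0, rep(10, 9))
  s <- kinetic_series(t, z_signal = 2 * e, e_signal = e)
  curve <- build_ratio_series(s, min_signal_fraction = 0.01)
  expect_identical(nrow(curve), 9L)          # the zero-signal point is gone
  expect_true(all(curve$ratio == 2))
  expect_true(all(is.finite(curve$ratio)))
  # fewer than 4 surviving points
  s2 <- kinetic_series(0:4, z_signal = c(0, 0, 1, 2, 2),
                       e_signal = c(0, 0, 0, 1, 1))
  expect_error(build_ratio_series(s2, 0.5), "insufficient")
})

test_that("noiseless trajectories reduce to the simulated concentration ratio", {
  k <- example_rates()
  design <- experiment_design(noise_rel_sd = 0, seed = 5)
  series <- generate_experiment(k, design)
  curve <- build_ratio_series(series)
  traj <- simulate_network(k, design$a0, design$l0,
                           c(0, curve$t_min))
  expect_equal(curve$ratio,
               (traj$Z_M / traj$E_M)[match(curve$t_min, traj$t_min)],
               tolerance = 1e-12)
})

test_that("exact exponential data are recovered to machine-level accuracy", {
  cases <- list(c(keq = 8, A = -6, c = 50),
                c(keq = 2.5, A = 4, c = 120),
                c(keq = 0.45, A = 0.8, c = 30))
  for (p in cases) {
    t <- seq(0, 400, length.out = 20)
    curve <- data.frame(t_min = t, ratio = p["keq"] + p["A"] * exp(-t / p["c"]))
    fit <- fit_ratio_exponential(curve, 1)
    expect_true(fit$converged)
    expect_lt(rel_err(fit$keq, p[["keq"]]), 1e-6)
    expect_lt(rel_err(fit$amplitudes, p[["A"]]), 1e-6)
    expect_lt(rel_err(fit$timescales, p[["c"]]), 1e-6)
    expect_lt(rel_err(fit$initial_ratio, p[["keq"]] + p[["A"]]), 1e-6)
  }
})

test_that("a constant ratio curve yields the degenerate fit", {
  t <- seq(0, 300, by = 20)
  fit <- fit_ratio_exponential(data.frame(t_min = t, ratio = rep(2, length(t))), 1)
  expect_equal(fit$keq, 2)
  expect_equal(fit$amplitudes, 0)
  expect_gt(fit$timescales, 0)
  expect_equal(fit$initial_ratio, 2)
  sel <- select_fit(data.frame(t_min = t, ratio = rep(2, length(t))))
  expect_identical(sel$n_exponentials, 1L)
  expect_equal(sel$amplitudes, 0)
})

test_that("model selection keeps one exponential on exact single-exponential data", {
  t <- seq(0, 400, length.out = 20)
  sel <- select_fit(data.frame(t_min = t, ratio = 8 - 6 * exp(-t / 50)))
  expect_identical(sel$n_exponentials, 1L)
})

test_that("well-separated two-exponential data select the double fit and recover it", {
  t <- seq(0, 600, length.out = 40)
  # timescales separated 10x, both amplitudes at least 20% of keq
  y <- 5 + 2.0 * exp(-t / 20) - 1.5 * exp(-t / 200)
  sel <- select_fit(data.frame(t_min = t, ratio = y))
  expect_identical(sel$n_exponentials, 2L)
  expect_lt(rel_err(sel$keq, 5), 1e-4)
  expect_lt(rel_err(sel$initial_ratio, 5.5), 1e-3)
  expect_equal(sort(sel$timescales), c(20, 200), tolerance = 1e-3)
})

test_that("fits are invariant to a common rescaling of both signals", {
  k <- example_rates()
  series <- generate_experiment(k, experiment_design(seed = 9))
  f1 <- select_fit(build_ratio_series(series))
  scaled <- kinetic_series(series$t_min, 137 * series$z_integral,
                           137 * series$e_integral)
  f2 <- select_fit(build_ratio_series(scaled))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("slow-regime noiseless curves recover the equilibrium constant within 1%", {
  ks <- sample_rate_constants("slow_bimolecular", 3, seed = 33)
  for (k in ks) {
    series <- generate_experiment(k, experiment_design(noise_rel_sd = 0))
    fit <- select_fit(build_ratio_series(series))
    expect_lt(rel_err(fit$keq, closed_form_ratios(k)$keq_ze), 0.01)
  }
})

test_that("data requirements are enforced", {
  expect_error(fit_ratio_exponential(
    data.frame(t_min = 0:2, ratio = c(1, 2, 3)), 1), "insufficient")
  expect_error(fit_ratio_exponential(
    data.frame(t_min = 0:4, ratio = rep(1, 5)), 2), "insufficient")
  expect_error(select_fit(data.frame(t_min = 0:4, ratio = rep(1, 5))),
               "insufficient")
})

test_that("ratio_fit methods expose coefficients, predictions and residuals", {
  t <- seq(0, 400, length.out = 25)
  y <- 8 - 6 * exp(-t / 50)
  fit <- fit_ratio_exponential(data.frame(t_min = t, ratio = y), 1)
  expect_named(coef(fit), c("keq", "A1", "c1"))
  expect_equal(predict(fit), y, tolerance = 1e-8)
  expect_equal(predict(fit, t = 0), 2, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_output(print(fit), "Keq")
  expect_output(print(summary(fit)), "kcal/mol")
})
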