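RT293 <- 1.98720e-3 * 293

test_that("free energies from Keq follow -RT ln Keq", {
  expect_identical(delta_g_from_keq(1, 293), 0)
  expect_equal(delta_g_from_keq(8.0, 293), -RT293 * log(8), tolerance = 1e-12)
  expect_equal(delta_g_from_keq(8.0, 293), -1.211, tolerance = 1e-3)
  expect_equal(delta_g_from_keq(0.45, 293), 0.465, tolerance = 1e-3)
  expect_error(delta_g_from_keq(0), "> 0")
  expect_error(delta_g_from_keq(-2), "> 0")
})

test_that("dG is antisymmetric under Keq inversion and decreasing in Keq", {
  k <- c(0.05, 0.45, 1, 1.3, 8, 20, 100)
  expect_equal(delta_g_from_keq(1 / k), -delta_g_from_keq(k),
               tolerance = 1e-12)
  expect_true(all(diff(delta_g_from_keq(sort(k))) < 0))
})

test_that("Keq error tiers are piecewise-constant, lower-inclusive, reciprocal below 1", {
  expect_identical(assign_keq_error_tier(3), 0.05)
  expect_identical(assign_keq_error_tier(20), 0.15)
  expect_identical(assign_keq_error_tier(0.45), 0.05)   # 1/0.45 ~ 2.2
  expect_identical(assign_keq_error_tier(c(5, 10, 15)), c(0.075, 0.10, 0.15))
  expect_identical(assign_keq_error_tier(0.08), 0.10)   # 1/0.08 = 12.5
  expect_error(assign_keq_error_tier(0), "> 0")
})

test_that("tier fractions translate into dG errors below the printed bounds", {
  expect_identical(dg_error_from_keq_error(0, 293), 0)
  expect_equal(dg_error_from_keq_error(0.05, 293), 0.0284, tolerance = 1e-2)
  expect_equal(dg_error_from_keq_error(0.15, 293), 0.0814, tolerance = 1e-2)
  bounds <- c(0.03, 0.05, 0.08, 0.10)
  fracs <- c(0.05, 0.075, 0.10, 0.15)
  expect_true(all(dg_error_from_keq_error(fracs, 293) <= bounds))
  expect_error(dg_error_from_keq_error(1.2), "\\[0, 1\\)")
  expect_error(dg_error_from_keq_error(-0.1), "\\[0, 1\\)")
})

test_that("quadrature propagation is symmetric and dominates each component", {
  expect_identical(propagate_dg_error(0, 0.07), 0.07)
  expect_identical(propagate_dg_error(0.03, 0.04), 0.05)
  expect_equal(propagate_dg_error(0.03, 0.03), 0.03 * sqrt(2),
               tolerance = 1e-12)
  expect_identical(propagate_dg_error(0.02, 0.05), propagate_dg_error(0.05, 0.02))
  expect_gte(propagate_dg_error(0.02, 0.05), 0.05)
  expect_error(propagate_dg_error(-0.01, 0.02), ">= 0")
})

test_that("interaction free energies reproduce the dichloromethane worked example", {
  m6 <- dg_ze_record(8.0, 293, "M6")
  r6 <- dg_ze_record(1.3, 293, "R6")
  r0 <- dg_ze_record(0.45, 293, "R0")
  dint_m6 <- interaction_free_energy(m6, r0)
  expect_equal(dint_m6$value, -RT293 * log(8.0 / 0.45), tolerance = 1e-12)
  expect_equal(dint_m6$value, -1.676, tolerance = 1e-3)
  dint_r6 <- interaction_free_energy(r6, r0)
  expect_equal(dint_r6$value, -RT293 * log(1.3 / 0.45), tolerance = 1e-12)
  expect_equal(dint_r6$value, -0.618, tolerance = 1e-3)
  dchg <- isostere_contribution(m6, r6, "charge")
  expect_equal(dchg$value, -RT293 * log(8.0 / 1.3), tolerance = 1e-12)
  expect_equal(dchg$value, -1.058, tolerance = 1e-3)
  expect_identical(dchg$quantity, "dG_charge")
  # errors propagate in quadrature from the tier-implied dG errors
  expect_equal(dint_m6$error,
               sqrt(m6$error^2 + r0$error^2), tolerance = 1e-12)
  # same-input differences vanish
  expect_identical(interaction_free_energy(m6, m6)$value, 0)
  expect_identical(isostere_contribution(r6, r6, "polarization")$value, 0)
})

test_that("differential quantities are antisymmetric and chain-consistent", {
  a <- dg_ze_record(6.2, 293, "A")
  b <- dg_ze_record(1.7, 293, "B")
  r0 <- dg_ze_record(0.45, 293, "R0")
  expect_equal(interaction_free_energy(a, b)$value,
               -interaction_free_energy(b, a)$value)
  # dG_int(model) - dG_int(isostere) equals the direct isostere subtraction
  chain <- interaction_free_energy(a, r0)$value -
    interaction_free_energy(b, r0)$value
  expect_equal(chain, isostere_contribution(a, b, "charge")$value,
               tolerance = 1e-15)
})

test_that("record pairing validates temperature and solvent", {
  a <- dg_ze_record(2, 293, "A", solvent = "DCM")
  b_temp <- dg_ze_record(2, 300, "B", solvent = "DCM")
  b_solv <- dg_ze_record(2, 293, "B", solvent = "MeCN")
  expect_error(interaction_free_energy(a, b_temp), "temperature")
  expect_error(interaction_free_energy(a, b_solv), "solvent")
  dint <- interaction_free_energy(a, dg_ze_record(1.1, 293, "R0",
                                                  solvent = "DCM"))
  expect_error(isostere_contribution(dint, a, "charge"), "dG_ZE")
})

test_that("class summaries report mean, spread and stability ordering", {
  s <- summarize_complex_class(c(-1, -1, -1), rep("cationic", 3))
  expect_equal(s$mean, -1)
  expect_equal(s$sd, 0)
  s2 <- summarize_complex_class(c(-1.2, -1.93), c("cationic", "cationic"))
  expect_equal(s2$mean, -1.565)
  expect_equal(s2$sd, 0.516, tolerance = 1e-3)
  s3 <- summarize_complex_class(c(-1.5, -1.7, -0.2, 0.3, 0.5),
                                c("cat", "cat", "non", "ani", "ani"))
  expect_identical(s3$class, c("cat", "non", "ani"))  # ascending mean
  expect_identical(s3$class[1], "cat")       # most negative mean first
  expect_true(is.na(s3$sd[s3$class == "non"]))
  f <- factor(c("a", "a"), levels = c("a", "b"))
  expect_warning(summarize_complex_class(c(-1, -2), f), "empty")
})
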