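test_that("step steady states follow the closed forms", {
  expect_equal(unname(predict_step_steady_state("DR08_M1_REV",
                                                list(k0 = 1, k2 = 2))["B"]),
               0.5)
  tc <- predict_step_steady_state("TC", list(k4 = 1, k3_tc = 2, Xt = 5,
                                             k1 = 1, k2 = 1), S = 1)
  expect_equal(unname(tc), c(0.5, 0.5, 4), tolerance = 1e-12)
  kr <- predict_step_steady_state("KR09",
                                  list(ka = 1, ki = 1, k_minus_a = 1,
                                       k_minus_i = 1, kf = 1, kr = 1,
                                       RT = 1), S = 3)
  expect_equal(unname(kr["Rstar"]), 0.5)
  expect_error(predict_step_steady_state("TC", list(Xt = 1), S = 1),
               "infeasible")
})

test_that("period-mean predictions cover maintained and unmaintained cases", {
  expect_equal(predict_period_mean("DR08_M1_REV", "B_to_A",
                                   list(k0 = 1, k2 = 1)), 1)
  expect_equal(predict_period_mean("DR08_M34", "A_to_B",
                                   list(k0 = 1, k3 = 1, k2 = 2)), 1)
  # derived closed form for the two-outflow motif
  expect_equal(predict_period_mean("DR08_M32", "A_to_B",
                                   list(k0 = 1, k2 = 1, k31 = 1, k33 = 1,
                                        k32 = 1)), 2 / 3)
  expect_true(is.na(predict_period_mean("DR08_M32", "B_to_C")))
  expect_true(is.na(predict_period_mean("KR09", "S_input")))
  expect_equal(predict_period_mean("TC", "A_to_B",
                                   list(k4 = 1, k3_tc = 2)), 0.5)
})

test_that("spatial-mean predictions respect diffusing species and sites", {
  expect_equal(predict_spatial_mean("DR08_M34", "A", "A_to_B",
                                    list(k0 = 1, k3 = 0, k2 = 1)), 1)
  expect_equal(predict_spatial_mean("HYB_XAI", "I", "dual_inflow_outflow",
                                    list(k0_h = 1, k2_h = 1, ka = 1,
                                         k_minus_a = 1, ki = 1,
                                         k_minus_i = 1)), 1)
  expect_true(is.na(predict_spatial_mean("TC", "A", "A_to_B")))
  expect_true(is.na(predict_spatial_mean("DR08_M32", c("A", "C"), "A_to_B")))
})

test_that("ramp rule table encodes the site restrictions", {
  expect_identical(predict_ramp_class("DR08_M1_REV", "B_to_A",
                                      "quadratic_ramp")$limit, 0)
  expect_identical(predict_ramp_class("DR08_M32", "C_to_A")$class,
                   "not_exact")
  expect_identical(predict_ramp_class("DR08_M32", "A_to_B")$class, "exact")
  expect_identical(predict_ramp_class("DR08_M34", "C_to_A")$class, "exact")
  expect_identical(predict_ramp_class("DR08_M34", "B_to_C")$class,
                   "not_exact")
  tcexp <- predict_ramp_class("TC", "A_to_B", "exponential")
  expect_identical(tcexp$class, "exact")
  expect_equal(tcexp$limit, 1)
  expect_identical(predict_ramp_class("KR09", "S_input",
                                      "exponential")$class, "not_exact")
  # fully reversible with two outflows: never exact
  expect_identical(predict_ramp_class("REV3", "A_to_B")$class, "not_exact")
  # with the C outflow removed, only B-degrading sites fail
  expect_identical(predict_ramp_class("REV3", "A_to_C",
                                      params = list(k33 = 0))$class, "exact")
  expect_identical(predict_ramp_class("REV3", "B_to_C",
                                      params = list(k33 = 0))$class,
                   "not_exact")
})

test_that("exponential-stimulus ratio: continuity, example, monotonicity", {
  p <- list(ka = 1, ki = 1, k_minus_a = 1, k_minus_i = 2)
  expect_equal(kr09_exponential_ratio(p, 1e-12)$ratio, 2, tolerance = 1e-9)
  expect_equal(kr09_exponential_ratio(list(ka = 1, ki = 1, k_minus_a = 1,
                                           k_minus_i = 2), 1)$ratio, 1.5)
  lam <- c(0.02, 0.05, 0.1, 0.3, 1)
  r0 <- kr09_exponential_ratio(p, 1e-12)$ratio
  dev <- abs(vapply(lam, function(l) kr09_exponential_ratio(p, l)$ratio,
                    numeric(1)) - r0)
  expect_true(all(diff(dev) > 0))
})

test_that("reverse-ramp slope formula and its limits", {
  expect_equal(two_node_reverse_ramp_slope(list(k0 = 1, k1 = 1, k2 = 1,
                                                k11 = 1), S1 = 1), 0.5)
  expect_equal(two_node_reverse_ramp_slope(list(), S1 = 1e9), 1,
               tolerance = 1e-8)
  expect_error(two_node_reverse_ramp_slope(list(k11 = 0), S1 = 1),
               "reverse site absent")
})

test_that("feedforward legs grow as predicted under a linear ramp", {
  m <- build_circuit("KR09")
  tr <- integrate_temporal(m, stimulus("linear_ramp", S1 = 0.1, t0 = 50),
                           t_end = 1050)
  n <- nrow(tr$conc)
  # A(t)/t -> ka S1 / k_minus_a
  a_over_t <- unname(tr$conc[n, "A"]) / (tr$times[n] - 50)
  expect_equal(a_over_t, 0.1, tolerance = 0.02)
})

test_that("derived two-outflow period mean is confirmed by simulation", {
  model <- build_circuit("DR08_M32", "A_to_B")
  T_ <- 2 * pi
  traj <- integrate_temporal(model, stimulus("sinusoid", a = 0.3, b = 0.15,
                                             w = 1, t0 = 0),
                             times = seq(0, 30 * T_, by = T_ / 128))
  mr <- temporal_period_mean(traj, period = T_)
  expect_true(mr$converged)
  expect_equal(mr$mean, predict_period_mean("DR08_M32", "A_to_B"),
               tolerance = 5e-3)
})
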