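test_that("a zero-size step is classified exact with zero precision", {
  m <- build_circuit("DR08_M1_IRREV", "A_to_B")
  tr <- integrate_temporal(m, stimulus("step", b = 0, t0 = 50), t_end = 120)
  rep <- classify_response(tr)
  expect_identical(rep$response_class, "exact")
  expect_equal(rep$precision, 0, tolerance = 1e-6)
})

test_that("classification is monotone in the exactness threshold", {
  # a non-adaptive case stays non-exact while an exact case stays exact as
  # eps_exact increases
  m <- build_circuit("DR08_M1_REV", "B_to_A")
  tr <- cached("m1rev_ramp", integrate_temporal(m, stimulus("linear_ramp"),
                                                t_end = 1050))
  for (eps in c(0.01, 0.05, 0.2)) {
    rep <- classify_response(tr, thresholds = list(eps_exact = eps))
    expect_false(rep$response_class == "exact")
  }
  fwd <- build_circuit("DR08_M1_REV", "A_to_B")
  tr2 <- integrate_temporal(fwd, stimulus("linear_ramp"), t_end = 1050)
  p <- classify_response(tr2)$precision
  for (eps in c(0.01, 0.05, 0.2)) {
    rep <- classify_response(tr2, thresholds = list(eps_exact = eps))
    expect_identical(rep$response_class, "exact")
    expect_equal(rep$precision, p)
  }
})

test_that("period means converge on an analytic trajectory", {
  # synthetic trajectory: y = 2 + sin(t), period 2*pi, mean exactly 2
  tt <- seq(0, 40 * pi, length.out = 8001)
  traj <- structure(list(
    times = tt,
    conc = cbind(B = 2 + sin(tt)),
    model = list(output = "B"),
    stim = structure(list(kind = "sinusoid", w = 1, t0 = 0, a = 1, b = 1),
                     class = "stimulus"),
    status = "completed"), class = "trajectory")
  mr <- temporal_period_mean(traj, period = 2 * pi)
  expect_true(mr$converged)
  expect_equal(mr$mean, 2, tolerance = 1e-6)
  aperiodic <- traj
  aperiodic$stim <- structure(list(kind = "linear_ramp", t0 = 0, a = 1,
                                   S1 = 0.1), class = "stimulus")
  expect_error(temporal_period_mean(aperiodic, period = NULL),
               "not periodic")
})

test_that("spatial means and local-mean profiles behave on synthetic fields", {
  nt <- 401; np <- 32
  tt <- seq(0, 8 * pi, length.out = nt)
  th <- seq(0, 1, length.out = np + 1)[1:np]
  # value v(theta, t) = 1 + 0.5 sin(2 pi theta) * sin(t): local temporal
  # means are exactly 1 everywhere; the final-time spatial mean is 1
  conc <- array(0, dim = c(nt, np, 1), dimnames = list(NULL, NULL, "B"))
  for (i in seq_len(nt)) conc[i, , 1] <- 1 + 0.5 * sin(2 * pi * th) * sin(tt[i])
  fld <- structure(list(times = tt, positions = th, conc = conc,
                        model = list(output = "B"),
                        stim = structure(list(kind = "standing_wave", w = 1,
                                              t0 = 0, a = 1, b = 0.5),
                                         class = "stimulus"),
                        status = "completed"), class = "stf_field")
  expect_equal(spatial_mean(fld, time = max(tt)), 1, tolerance = 1e-10)
  prof <- local_temporal_mean_profile(fld, period = 2 * pi)
  expect_lt(prof$uniformity, 1e-4)
  expect_equal(prof$level, 1, tolerance = 1e-5)
})

test_that("uniform fields report their value and zero variance", {
  m <- build_circuit("DR08_M1_REV")
  fld <- integrate_spatial(m, stimulus("step", b = 0.2, t0 = 5), n = 16,
                           t_end = 150)
  expect_equal(spatial_mean(fld), 1, tolerance = 1e-5)
  expect_lt(stats::sd(spatial_profile(fld)), 1e-8)
})
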