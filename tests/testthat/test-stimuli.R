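test_that("every stimulus family holds the basal level before onset", {
  kinds <- c("step", "linear_ramp", "capped_ramp", "quadratic_ramp",
             "exponential", "sinusoid")
  for (k in kinds) {
    sp <- stimulus(k, a = 0.1, t0 = 50)
    expect_equal(evaluate_stimulus(sp, 40), 0.1, info = k)
  }
  for (k in c("static_gradient", "spatial_ramp", "travelling_wave",
              "standing_wave")) {
    sp <- stimulus(k, a = 0.1, b = 0.05, t0 = 50)
    expect_equal(evaluate_stimulus(sp, 40, theta = 0.3), 0.1, info = k)
  }
})

test_that("closed forms evaluate correctly", {
  expect_equal(evaluate_stimulus(stimulus("sinusoid", a = 1, b = 0.5,
                                          w = 1, t0 = 0), pi / 2), 1.5)
  expect_equal(evaluate_stimulus(stimulus("capped_ramp", a = 0.1, S1 = 1,
                                          Smax = 2, t0 = 0), 10), 2)
  expect_equal(evaluate_stimulus(stimulus("linear_ramp", a = 0.1, S1 = 0.1,
                                          t0 = 50), 60), 1.1)
  expect_equal(evaluate_stimulus(stimulus("quadratic_ramp", a = 0.1,
                                          S1 = 0.1, t0 = 0), 3), 1)
  expect_equal(evaluate_stimulus(stimulus("exponential", a = 0.1,
                                          lambda = 0.5, t0 = 0), 2),
               0.1 * exp(1))
})

test_that("stimulus periods are reported for periodic kinds only", {
  expect_equal(stimulus_period(stimulus("sinusoid", w = 2 * pi)), 1)
  expect_equal(stimulus_period(stimulus("travelling_wave", w = pi)), 2)
  expect_null(stimulus_period(stimulus("linear_ramp")))
  expect_null(stimulus_period(stimulus("static_gradient")))
})

test_that("positivity validation catches violating amplitudes", {
  bad <- structure(list(kind = "sinusoid", a = 1, b = 2, w = 1, t0 = 0),
                   class = "stimulus")
  expect_match(validate_positivity(bad), "exceeds basal")
  expect_true(validate_positivity(stimulus("sinusoid", a = 1, b = 1)))
  expect_true(validate_positivity(stimulus("standing_wave", a = 1, b = 0.5)))
  expect_error(stimulus("sinusoid", a = 1, b = 2), "negative")
})

test_that("position argument is required iff the kind is spatial", {
  expect_error(evaluate_stimulus(stimulus("sinusoid"), 1, theta = 0.5),
               "no position")
  expect_error(evaluate_stimulus(stimulus("standing_wave"), 1),
               "requires a position")
  expect_error(evaluate_stimulus(stimulus("standing_wave"), 1, theta = 1.5),
               "\\[0, L\\)")
})

test_that("travelling wave advects: S(theta, t) = S(theta - c dt, t - dt)", {
  sp <- stimulus("travelling_wave", a = 1, b = 0.5, w = 2, m = 2, L = 1,
                 t0 = 0)
  cvel <- sp$w * sp$L / (2 * pi * sp$m)
  th <- seq(0, 1, length.out = 65)[1:64]
  for (dt in c(0.1, 0.37)) {
    s1 <- evaluate_stimulus(sp, 5, th)
    s0 <- evaluate_stimulus(sp, 5 - dt, (th - cvel * dt) %% sp$L)
    expect_equal(s1, s0, tolerance = 1e-12)
  }
})

test_that("standing wave nodes keep the basal temporal mean", {
  sp <- stimulus("standing_wave", a = 1, b = 0.8, w = 2, m = 1, L = 1,
                 t0 = 0)
  tt <- seq(0, 2 * pi / sp$w, length.out = 2001)
  # node: sin(2 pi m theta / L) = 0 at theta = 0 (signal constant at a)
  expect_equal(evaluate_stimulus(sp, tt, rep(0, length(tt))),
               rep(1, length(tt)))
  # antinode: temporal mean over a full period is still a
  sv <- evaluate_stimulus(sp, tt, rep(0.25, length(tt)))
  expect_equal(mean(sv[-1]), 1, tolerance = 1e-6)
})

test_that("circuit + stimulus configurations round-trip through YAML", {
  m <- build_circuit("DR08_M34", "B_to_A", list(k2 = 2),
                     diffusivities = c(A = 0.5))
  sp <- stimulus("travelling_wave", a = 0.4, b = 0.2, w = 2, m = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(path, m, sp)
  back <- read_config(path)
  expect_equal(back$model$params, m$params)
  expect_equal(back$model$signal_site, m$signal_site)
  expect_equal(back$model$diffusivities, m$diffusivities)
  expect_equal(unclass(back$stim), unclass(sp))
  # rhs closures must agree after the round trip
  st <- c(A = 1, B = 2, C = 0.5)
  expect_equal(evaluate_rhs(back$model, st, 1.7),
               evaluate_rhs(m, st, 1.7))
})
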