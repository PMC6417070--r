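test_that("registry builds models with defaults and validates inputs", {
  m <- build_circuit("DR08_M1_REV", "A_to_B")
  expect_s3_class(m, "circuit_model")
  expect_identical(m$species, c("A", "B"))
  expect_identical(m$output, "B")
  expect_equal(unname(m$params["k11"]), 1)

  expect_error(build_circuit("NOPE"), "unknown model_id")
  expect_error(build_circuit("DR08_M1_IRREV", "C_to_A"), "invalid signal site")
  expect_error(build_circuit("DR08_M1_REV", "A_to_B", list(zz = 1)),
               "unknown parameter")
  expect_error(build_circuit("DR08_M1_REV", "A_to_B", list(k1 = -1)),
               "nonnegative")
})

test_that("transcritical feasibility bound is enforced at the basal signal", {
  expect_error(
    build_circuit("TC", "A_to_B",
                  list(Xt = 0.1, k4 = 1, k3_tc = 1, k2 = 1, k1 = 1),
                  s_basal = 0.1),
    "infeasible")
  # bound at S = 0.1 is 11; just above it must build
  expect_s3_class(
    build_circuit("TC", "A_to_B", list(Xt = 11.5), s_basal = 0.1),
    "circuit_model")
})

test_that("right-hand sides evaluate the model equations exactly", {
  m <- build_circuit("DR08_M1_IRREV", "A_to_B")
  expect_equal(evaluate_rhs(m, c(A = 1, B = 1), 1), c(A = 0, B = 0))

  tc <- build_circuit("TC")
  d <- evaluate_rhs(tc, c(A = 0.7, B = 1, C = 2.3), 0.5)
  expect_equal(unname(d["C"]), 0)  # dC/dt = C(k3_tc B - k4) = 0 at B = k4/k3

  k <- build_circuit("KR09", overrides = list(ka = 2, k_minus_a = 1))
  d <- evaluate_rhs(k, c(A = 0, I = 0, Rstar = 0), 1)
  expect_equal(unname(d["A"]), 2)

  expect_error(evaluate_rhs(m, c(1, 2, 3), 1), "species count")
  expect_error(evaluate_rhs(m, c(A = -1, B = 1), 1), "nonnegative")
})

test_that("the signal multiplies only the configured reaction", {
  fwd <- build_circuit("DR08_M1_REV", "A_to_B")
  rev <- build_circuit("DR08_M1_REV", "B_to_A")
  s <- c(A = 2, B = 3)
  # forward site: dA = k0 - k1*S*A + k11*B
  expect_equal(unname(evaluate_rhs(fwd, s, 5)["A"]), 1 - 5 * 2 + 3)
  # reverse site: dA = k0 - k1*A + k11*S*B
  expect_equal(unname(evaluate_rhs(rev, s, 5)["A"]), 1 - 2 + 5 * 3)
})

test_that("conserved total exists for the closed circuit only", {
  tc <- build_circuit("TC")
  expect_equal(conserved_total(tc, c(1, 2, 3)), 6)
  expect_null(conserved_total(build_circuit("DR08_M1_REV"), c(1, 2)))
})

test_that("signal-site listings match the topologies", {
  expect_setequal(list_signal_sites("DR08_M1_IRREV"),
                  c("A_to_B", "B_outflow"))
  expect_setequal(list_signal_sites("DR08_M34"),
                  c("A_to_B", "B_to_A", "B_to_C", "C_to_A", "B_outflow"))
  expect_identical(list_signal_sites("KR09"), "S_input")
  expect_error(list_signal_sites("XX"), "unknown model_id")
})

test_that("no derivative drives a zero-valued species negative", {
  set.seed(11)
  models <- all_default_models()
  for (model in models) {
    for (rep in 1:40) {
      st <- random_state(model)
      j <- sample(length(st), 1)
      st[j] <- 0
      d <- evaluate_rhs(model, st, stats::runif(1, 0, 5))
      expect_gte(d[[j]], 0)
    }
  }
})

test_that("TC dynamics conserve A+B+C at arbitrary states and signals", {
  set.seed(7)
  for (site in c("A_to_B", "B_to_A")) {
    tc <- build_circuit("TC", site)
    for (rep in 1:50) {
      d <- evaluate_rhs(tc, random_state(tc), stats::runif(1, 0, 5))
      expect_lt(abs(sum(d)), 1e-12)
    }
  }
})

test_that("mass-balance identities hold identically", {
  set.seed(23)
  m1 <- build_circuit("DR08_M1_REV", "A_to_B")
  m34 <- build_circuit("DR08_M34", "A_to_B")
  for (rep in 1:50) {
    s1 <- random_state(m1); sig <- stats::runif(1, 0, 5)
    d1 <- evaluate_rhs(m1, s1, sig)
    expect_equal(sum(d1), 1 - s1[["B"]])          # d(A+B) = k0 - k2 B
    s3 <- random_state(m34)
    d3 <- evaluate_rhs(m34, s3, sig)
    expect_equal(sum(d3), 1 + 1 - s3[["B"]])      # d(A+B+C) = k0 + k3 - k2 B
  }
})

test_that("vectorized rhs evaluation matches per-state evaluation", {
  m <- build_circuit("DR08_M34", "A_to_B")
  st <- matrix(stats::runif(12, 0.1, 2), nrow = 4, ncol = 3,
               dimnames = list(NULL, m$species))
  sig <- stats::runif(4, 0, 2)
  d <- evaluate_rhs(m, st, sig)
  for (i in 1:4) {
    expect_equal(d[i, ], evaluate_rhs(m, st[i, ], sig[i]))
  }
})
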