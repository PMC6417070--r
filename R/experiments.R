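# ---------------------------------------------------------------------------
# Named, reproducible experiments: circuit + stimulus + metrics + oracle.
#
# Every experiment is a deterministic function of its configuration; the
# full suite reproduces the qualitative circuit-by-stimulus combination
# matrix (exact ramp adaptation / period-mean maintenance / spatial-mean
# maintenance) for the eight canonical circuit instantiations.
# ---------------------------------------------------------------------------

.basal_of <- function(model_id) .get_entry(model_id)$s_basal

# ---- reusable experiment engines ------------------------------------------

#' Simulate a ramp response and compare with the rule-table oracle
#'
#' @param model_id,signal_site Circuit instantiation.
#' @param kind Ramp kind (\code{linear_ramp}, \code{quadratic_ramp},
#'   \code{exponential}, \code{capped_ramp}).
#' @param t_end Final time (default onset + 1000).
#' @param stim_args Extra stimulus arguments (slope, exponent, cap, ...).
#' @param overrides Circuit parameter overrides.
#' @return List with the trajectory's \code{response_report}, the oracle
#'   \code{prediction}, and \code{agrees} (simulated class matches the
#'   predicted exact/not-exact verdict).
#' @export
ramp_response <- function(model_id, signal_site, kind = "linear_ramp",
                          t_end = NULL, stim_args = list(),
                          overrides = list()) {
  model <- build_circuit(model_id, signal_site, overrides)
  args <- c(list(kind = kind), stim_args,
            list(a = .basal_of(model_id), t0 = 50))
  args <- args[!duplicated(names(args))]
  stim <- do.call(stimulus, args)
  traj <- integrate_temporal(model, stim, t_end = t_end)
  rep <- classify_response(traj)
  pred <- predict_ramp_class(model_id, signal_site,
                             if (kind == "capped_ramp") "linear_ramp"
                             else kind,
                             overrides)
  agrees <- (rep$response_class == "exact") == (pred$class == "exact")
  list(report = rep, prediction = pred, agrees = agrees, trajectory = traj)
}

#' Period means of the output over a sweep of stimulus settings
#'
#' Runs a sinusoidal stimulus at each (basal, amplitude) pair, computes the
#' converged period mean of the output, and compares against the analytic
#' prediction where one exists.
#'
#' @param model_id,signal_site Circuit instantiation.
#' @param sweep Data frame or list of \code{(a, b)} pairs.
#' @param w Angular frequency.
#' @param cycles Number of stimulus cycles to integrate.
#' @param overrides Circuit parameter overrides.
#' @return List with per-setting \code{means}, the \code{prediction}
#'   (\code{NA} when not maintained), \code{max_rel_dev} from the prediction,
#'   \code{spread} (relative range across the sweep) and \code{maintained}.
#' @export
period_mean_sweep <- function(model_id, signal_site,
                              sweep = data.frame(a = c(0.2, 0.4),
                                                 b = c(0.1, 0.2)),
                              w = 1, cycles = 40, overrides = list()) {
  sweep <- as.data.frame(sweep)
  T_ <- 2 * pi / w
  means <- numeric(nrow(sweep))
  for (i in seq_len(nrow(sweep))) {
    model <- build_circuit(model_id, signal_site, overrides,
                           s_basal = sweep$a[i])
    stim <- stimulus("sinusoid", a = sweep$a[i], b = sweep$b[i], w = w,
                     t0 = 0)
    times <- seq(0, cycles * T_, by = T_ / 128)
    traj <- integrate_temporal(model, stim, times = times)
    mr <- temporal_period_mean(traj, period = T_)
    if (!mr$converged) {
      stop("period mean did not converge for ", model_id, " at a = ",
           sweep$a[i], ", b = ", sweep$b[i], call. = FALSE)
    }
    means[i] <- mr$mean
  }
  pred <- predict_period_mean(model_id, signal_site, overrides)
  spread <- (max(means) - min(means)) / abs(mean(means))
  max_rel_dev <- if (is.na(pred)) NA_real_ else max(abs(means - pred) / pred)
  maintained <- spread < 0.01 && (is.na(pred) || max_rel_dev < 0.01)
  list(sweep = sweep, means = means, prediction = pred,
       max_rel_dev = max_rel_dev, spread = spread, maintained = maintained)
}

#' Spatial mean of the output in a static spatial gradient
#'
#' Equilibrates at the basal level, switches on a static sinusoidal gradient
#' and integrates the reaction-diffusion system to (quasi) steady state.
#' The mean is "maintained" when the spatial mean of the output stays within
#' 1\% of its pre-gradient adapted level (which equals the analytic
#' prediction for maintaining circuits).
#'
#' @param model_id,signal_site Circuit instantiation.
#' @param diffusivities Named diffusivity vector.
#' @param a,b Basal level and gradient amplitude.
#' @param n Grid size.
#' @param t_end Integration horizon after onset.
#' @param m Spatial mode.
#' @param overrides Circuit parameter overrides.
#' @return List with \code{mean} (spatial mean of output), \code{cv}
#'   (spatial coefficient of variation: graded response when > 0),
#'   \code{baseline}, \code{prediction}, \code{rel_dev}, \code{maintained},
#'   and the \code{field}.
#' @export
spatial_gradient_response <- function(model_id, signal_site, diffusivities,
                                      a = NULL, b = NULL, n = 128,
                                      t_end = 300, m = 1,
                                      overrides = list()) {
  if (is.null(a)) a <- pmax(.basal_of(model_id), 0.2)
  if (is.null(b)) b <- a / 2
  model <- build_circuit(model_id, signal_site, overrides,
                         diffusivities = diffusivities, s_basal = a)
  stim <- stimulus("static_gradient", a = a, b = b, m = m, t0 = 0)
  field <- integrate_spatial(model, stim, n = n, t_end = t_end)
  prof <- spatial_profile(field)
  baseline <- field$basal_state[[model$output]]
  pred <- predict_spatial_mean(model_id,
                               names(diffusivities)[unlist(diffusivities) > 0],
                               signal_site, overrides)
  sm <- mean(prof)
  list(mean = sm, cv = stats::sd(prof) / sm, baseline = baseline,
       prediction = pred, rel_dev = abs(sm - baseline) / abs(baseline),
       maintained = abs(sm - baseline) / abs(baseline) < 0.01,
       field = field)
}

#' Local temporal means under a travelling or standing wave
#'
#' @param model_id,signal_site Circuit instantiation.
#' @param diffusivities Named diffusivity vector.
#' @param kind \code{"travelling_wave"} or \code{"standing_wave"}.
#' @param a,b,w,m Wave parameters.
#' @param n Grid size.
#' @param cycles Number of periods integrated.
#' @param overrides Circuit parameter overrides.
#' @return The [local_temporal_mean_profile()] list, augmented with the
#'   analytic \code{prediction} for the maintained level (or \code{NA}).
#' @export
wave_response <- function(model_id, signal_site, diffusivities,
                          kind = "travelling_wave", a = 0.5, b = 0.25,
                          w = 1, m = 1, n = 128, cycles = 25,
                          overrides = list()) {
  model <- build_circuit(model_id, signal_site, overrides,
                         diffusivities = diffusivities, s_basal = a)
  stim <- stimulus(kind, a = a, b = b, w = w, m = m, t0 = 0)
  T_ <- stimulus_period(stim)
  times <- seq(0, cycles * T_, by = T_ / 64)
  field <- integrate_spatial(model, stim, n = n, times = times)
  prof <- local_temporal_mean_profile(field, period = T_)
  prof$prediction <- predict_period_mean(model_id, signal_site, overrides)
  prof$field <- field
  prof
}

# ---- experiment registry ---------------------------------------------------

.experiments <- new.env(parent = emptyenv())

.def_exp <- function(name, description, fn) {
  assign(name, list(name = name, description = description, fn = fn),
         envir = .experiments)
}

#' Names of the registered experiments
#' @return Character vector.
#' @export
list_experiments <- function() sort(ls(.experiments))

#' Run one registered experiment
#'
#' @param name One of [list_experiments()].
#' @param overrides Named list forwarded to the experiment definition
#'   (circuit parameter overrides).
#' @return The experiment's report list; always contains \code{name},
#'   \code{pass} (oracle agreement) and experiment-specific quantities.
#' @export
run_experiment <- function(name, overrides = list()) {
  if (!exists(name, envir = .experiments, inherits = FALSE)) {
    stop("unknown experiment '", name, "'; see list_experiments()",
         call. = FALSE)
  }
  e <- get(name, envir = .experiments, inherits = FALSE)
  out <- e$fn(overrides)
  out$name <- name
  out$description <- e$description
  out
}

.def_exp("ramp_dr08m1_forward",
         "two-node motif, linear ramp on A->B: exact adaptation",
         function(ov) {
  r <- ramp_response("DR08_M1_IRREV", "A_to_B", overrides = ov)
  list(class = r$report$response_class, precision = r$report$precision,
       steady = r$report$steady_value, expected = r$prediction$limit,
       pass = r$agrees && r$report$response_class == "exact")
})

.def_exp("ramp_dr08m1_reverse",
         "two-node motif, linear ramp on B->A: non-adaptive steady state, A grows linearly",
         function(ov) {
  r <- ramp_response("DR08_M1_REV", "B_to_A", t_end = 1050, overrides = ov)
  det <- detect_steady_state(r$trajectory, "A")
  slope_pred <- two_node_reverse_ramp_slope(ov, S1 = r$trajectory$stim$S1)
  list(class = r$report$response_class, a_growth = det$growth_class,
       a_rate = det$rate, slope_pred = slope_pred,
       slope_rel_err = abs(det$rate - slope_pred) / slope_pred,
       pass = r$report$response_class == "nonadaptive_steady" &&
         det$growth_class == "linear_growth" &&
         abs(det$rate - slope_pred) / slope_pred < 0.02)
})

.def_exp("ramp_dr08m1_reverse_quadratic",
         "two-node motif, quadratic ramp on B->A: output driven to zero",
         function(ov) {
  r <- ramp_response("DR08_M1_REV", "B_to_A", kind = "quadratic_ramp",
                     t_end = 50 + 20000, overrides = ov)
  list(class = r$report$response_class, steady = r$report$steady_value,
       baseline = r$report$baseline,
       pass = abs(r$report$steady_value) < 1e-3 * r$report$baseline)
})

.def_exp("ramp_capped_dr08m1",
         "capping a ramp after adaptation completes leaves the response unchanged",
         function(ov) {
  model <- build_circuit("DR08_M1_IRREV", "A_to_B", ov)
  t_end <- 1050
  times <- seq(0, t_end, length.out = 2001)
  uncapped <- integrate_temporal(model, stimulus("linear_ramp"),
                                 times = times)
  # adaptation residual decays as S1/S^2; a cap of 5 engages at t ~ 99,
  # once the output has re-adapted to within ~0.4% of baseline
  capped <- integrate_temporal(model,
                               stimulus("capped_ramp", Smax = 5),
                               times = times)
  rep <- classify_response(capped)
  peak <- rep$peak_deviation
  maxdiff <- max(abs(capped$conc[, "B"] - uncapped$conc[, "B"]))
  list(class = rep$response_class, max_traj_diff = maxdiff,
       peak_deviation = peak, rel_diff = maxdiff / peak,
       pass = rep$response_class == "exact" && maxdiff < 0.01 * peak)
})

.def_exp("ramp_dr08m32_sites",
         "two-outflow three-node motif: only the A->B site adapts exactly in a ramp",
         function(ov) {
  sites <- list_signal_sites("DR08_M32")
  res <- lapply(sites, function(s) {
    ramp_response("DR08_M32", s, overrides = ov)
  })
  classes <- vapply(res, function(r) r$report$response_class, "")
  exact <- classes == "exact"
  names(exact) <- sites
  list(classes = stats::setNames(classes, sites), exact = exact,
       pass = identical(unname(exact), sites == "A_to_B"))
})

.def_exp("ramp_dr08m34_sites",
         "one-outflow three-node motif: exact in a ramp unless the signal converts/degrades B",
         function(ov) {
  sites <- c("A_to_B", "B_to_A", "B_to_C", "C_to_A")
  res <- lapply(sites, function(s) {
    ramp_response("DR08_M34", s, overrides = ov)
  })
  classes <- vapply(res, function(r) r$report$response_class, "")
  exact <- stats::setNames(classes == "exact", sites)
  list(classes = stats::setNames(classes, sites), exact = exact,
       pass = identical(unname(exact), sites %in% c("A_to_B", "C_to_A")))
})

.def_exp("ramp_tc",
         "transcritical circuit adapts exactly to linear, quadratic and exponential stimuli",
         function(ov) {
  kinds <- c("linear_ramp", "quadratic_ramp", "exponential")
  res <- lapply(kinds, function(k) {
    ramp_response("TC", "A_to_B", kind = k,
                  t_end = if (k == "exponential") 150 else NULL,
                  stim_args = if (k == "exponential") list(lambda = 0.1)
                              else list(),
                  overrides = ov)
  })
  classes <- stats::setNames(vapply(res, function(r)
    r$report$response_class, ""), kinds)
  list(classes = classes, pass = all(classes == "exact"))
})

.def_exp("ramp_kr09",
         "feedforward motif adapts exactly to linear and quadratic ramps",
         function(ov) {
  kinds <- c("linear_ramp", "quadratic_ramp")
  res <- lapply(kinds, function(k) {
    ramp_response("KR09", "S_input", kind = k, overrides = ov)
  })
  classes <- stats::setNames(vapply(res, function(r)
    r$report$response_class, ""), kinds)
  list(classes = classes, pass = all(classes == "exact"))
})

.def_exp("kr09_exponential_sweep",
         "feedforward motif under exponentials: deviation grows with the exponent and matches the limiting A/I ratio",
         function(ov) {
  lambdas <- c(0.05, 0.1, 0.2)
  base <- predict_step_steady_state("KR09", ov, S = 1)[["Rstar"]]
  sim <- vapply(lambdas, function(l) {
    r <- ramp_response("KR09", "S_input", kind = "exponential",
                       t_end = 200, stim_args = list(lambda = l),
                       overrides = ov)
    r$report$steady_value
  }, numeric(1))
  pred <- vapply(lambdas, function(l)
    kr09_exponential_ratio(ov, l)$Rstar, numeric(1))
  dev_sim <- abs(sim - base)
  rel_err <- abs(sim - pred) / pred
  list(lambda = lambdas, simulated = sim, predicted = pred,
       baseline = base, deviation = dev_sim, rel_err = rel_err,
       monotone = all(diff(dev_sim) > 0),
       pass = all(rel_err < 0.02) && all(diff(dev_sim) > 0))
})

.def_exp("reverse_ramp_slope",
         "linear growth rate of A under a reverse-site ramp matches the asymptotic prediction",
         function(ov) {
  r <- ramp_response("DR08_M1_REV", "B_to_A", t_end = 1050, overrides = ov)
  det <- detect_steady_state(r$trajectory, "A")
  pred <- two_node_reverse_ramp_slope(ov, S1 = r$trajectory$stim$S1)
  list(rate = det$rate, predicted = pred,
       rel_err = abs(det$rate - pred) / pred,
       pass = abs(det$rate - pred) / pred < 0.02)
})

.def_exp("period_mean_dr08m1",
         "two-node motif maintains the period mean of B at k0/k2 (signal on A->B or B->A)",
         function(ov) {
  fwd <- period_mean_sweep("DR08_M1_REV", "A_to_B", overrides = ov)
  rev <- period_mean_sweep("DR08_M1_REV", "B_to_A", overrides = ov)
  list(forward = fwd, reverse = rev,
       pass = fwd$maintained && rev$maintained &&
         fwd$max_rel_dev < 0.005 && rev$max_rel_dev < 0.005)
})

.def_exp("period_mean_dr08m34",
         "one-outflow three-node motif maintains the period mean at (k0+k3)/k2",
         function(ov) {
  r <- period_mean_sweep("DR08_M34", "A_to_B", overrides = ov)
  list(result = r, pass = r$maintained && r$max_rel_dev < 0.005)
})

.def_exp("period_mean_dr08m32",
         "two-outflow motif: period mean of B fixed, and mean(k2 B + k33 C) = k0",
         function(ov) {
  model <- build_circuit("DR08_M32", "A_to_B", ov)
  p <- as.list(model$params)
  T_ <- 2 * pi
  stim <- stimulus("sinusoid", a = 0.3, b = 0.15, w = 1, t0 = 0)
  times <- seq(0, 40 * T_, by = T_ / 128)
  traj <- integrate_temporal(model, stim, times = times)
  mB <- temporal_period_mean(traj, period = T_, species = "B")$mean
  mC <- temporal_period_mean(traj, period = T_, species = "C")$mean
  combo <- p$k2 * mB + p$k33 * mC
  pred <- predict_period_mean("DR08_M32", "A_to_B", ov)
  sweep <- period_mean_sweep("DR08_M32", "A_to_B", overrides = ov)
  list(mean_B = mB, mean_C = mC, combo = combo, k0 = p$k0,
       prediction = pred, sweep = sweep,
       combo_rel_err = abs(combo - p$k0) / p$k0,
       pass = abs(combo - p$k0) / p$k0 < 0.005 &&
         sweep$maintained && sweep$max_rel_dev < 0.005)
})

.def_exp("period_mean_tc",
         "transcritical circuit maintains the period mean of B at k4/k3_tc",
         function(ov) {
  r <- period_mean_sweep("TC", "A_to_B",
                         sweep = data.frame(a = c(0.5, 1.0),
                                            b = c(0.2, 0.4)),
                         overrides = ov)
  list(result = r, pass = r$maintained && r$max_rel_dev < 0.005)
})

.def_exp("period_mean_kr09_sweep",
         "feedforward motif does not maintain the period mean across a basal sweep",
         function(ov) {
  # fixed amplitude, 10x basal sweep; amplitude = the largest level
  # admissible (positivity) at the lowest basal
  r <- period_mean_sweep("KR09", "S_input",
                         sweep = data.frame(a = c(0.1, 1.0),
                                            b = c(0.1, 0.1)),
                         overrides = ov)
  list(result = r, spread = r$spread, pass = r$spread > 0.05)
})

.def_exp("spatial_gradient_dr08m34",
         "one-outflow motif with diffusible A: graded response, spatial mean maintained",
         function(ov) {
  r <- spatial_gradient_response("DR08_M34", "A_to_B", c(A = 1),
                                 overrides = ov)
  r$field <- NULL
  r$pass <- r$maintained && r$cv > 0.01
  r
})

.def_exp("spatial_gradient_hyb_xai",
         "hybrid inflow/outflow circuit maintains the spatial mean of X",
         function(ov) {
  r <- spatial_gradient_response("HYB_XAI", "dual_inflow_outflow",
                                 c(I = 20), overrides = ov)
  r$field <- NULL
  r$pass <- r$maintained && r$rel_dev < 0.005
  r
})

.def_exp("spatial_gradient_tc",
         "transcritical circuit with diffusible A does not maintain the spatial mean",
         function(ov) {
  r <- spatial_gradient_response("TC", "A_to_B", c(A = 1), a = 0.5,
                                 b = 0.25, t_end = 600, overrides = ov)
  r$field <- NULL
  r$pass <- r$rel_dev > 0.01
  r
})

# Wave experiments use a moderately diffusible A (kd = 0.025): the diffusion
# length over one stimulus period, sqrt(kd * 2pi/w) ~ 0.4 L, is comparable to
# the wavelength, so spatial coupling neither vanishes nor homogenizes the
# time-averaged field.
.def_exp("wave_travelling_dr08m34",
         "one-outflow motif, diffusible A: travelling wave leaves a uniform local temporal mean",
         function(ov) {
  r <- wave_response("DR08_M34", "A_to_B", c(A = 0.025), "travelling_wave",
                     b = 0.45, overrides = ov)
  r$field <- NULL
  r$level_rel_err <- abs(r$level - r$prediction) / r$prediction
  r$pass <- r$uniformity < 0.01 && r$level_rel_err < 0.01
  r
})

.def_exp("wave_standing_dr08m34",
         "one-outflow motif, diffusible A: standing wave makes local means vary, spatial average still fixed",
         function(ov) {
  r <- wave_response("DR08_M34", "A_to_B", c(A = 0.025), "standing_wave",
                     b = 0.45, overrides = ov)
  r$field <- NULL
  r$level_rel_err <- abs(r$level - r$prediction) / r$prediction
  r$pass <- r$uniformity > 0.05 && r$level_rel_err < 0.01
  r
})

.def_exp("wave_tc",
         "transcritical circuit (A diffusible, C weakly diffusible) keeps local means near k4/k3_tc for both wave types",
         function(ov) {
  kinds <- c("travelling_wave", "standing_wave")
  res <- lapply(kinds, function(k) {
    r <- wave_response("TC", "A_to_B", c(A = 1, C = 0.1), k,
                       overrides = ov)
    r$field <- NULL
    r
  })
  pred <- res[[1]]$prediction
  maxdev <- max(vapply(res, function(r)
    max(abs(r$local_means - pred) / pred), numeric(1)))
  list(travelling = res[[1]], standing = res[[2]], prediction = pred,
       max_local_dev = maxdev, pass = maxdev < 0.02)
})

.def_exp("spatial_ramp_dr08m34_local",
         "no diffusion: a spatially varying ramp on B->A yields a steady, spatially graded response",
         function(ov) {
  model <- build_circuit("DR08_M34", "B_to_A", ov)
  stim <- stimulus("spatial_ramp", a = 0.1, S1 = 0.1, eps = 0.5, m = 1,
                   t0 = 0)
  field <- integrate_spatial(model, stim, n = 64, t_end = 600)
  prof <- spatial_profile(field)
  nt <- length(field$times)
  prev <- field$conc[nt - 1L, , "B"]
  dt_last <- field$times[nt] - field$times[nt - 1L]
  drift <- max(abs(prof - prev)) / dt_last / max(prof)
  list(cv = stats::sd(prof) / mean(prof), drift = drift,
       profile_range = range(prof),
       pass = drift < 1e-4 && stats::sd(prof) / mean(prof) > 0.01)
})

# ---- combination matrix ----------------------------------------------------

#' Canonical circuit instantiations for the combination matrix
#'
#' Eight circuit instantiations, each probing one combination of exact ramp
#' adaptation, period-mean maintenance and static-gradient spatial-mean
#' maintenance.
#'
#' @return Data frame with columns \code{row}, \code{model_id},
#'   \code{signal_site}, \code{diffusible}, \code{kd}, and the expected
#'   verdicts \code{ramp}, \code{periodic}, \code{spatial}.
#' @export
combination_rows <- function() {
  # row 2: two outflows with the signal mediating the reaction between the
  # two outflow variables (B -> C) - the combination that fails all three
  data.frame(
    row = c("one_outflow_signal_upstream", "two_outflows_signal_between",
            "one_outflow_signal_on_output", "incoherent_feedforward",
            "transcritical_forward", "transcritical_reverse",
            "hybrid_dual_regulation", "hybrid_dual_s2"),
    model_id = c("DR08_M34", "DR08_M32", "DR08_M1_REV", "KR09", "TC", "TC",
                 "HYB_XAI", "HYB_S2"),
    signal_site = c("A_to_B", "B_to_C", "B_to_A", "S_input", "A_to_B",
                    "B_to_A", "dual_inflow_outflow", "dual_inflow_outflow"),
    diffusible = c("A", "A", "A", "I", "A", "A", "I", "I"),
    kd = c(1, 1, 1, 20, 1, 1, 20, 20),
    ramp = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    periodic = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    spatial = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

.matrix_periodic_sweep <- function(model_id) {
  # ratio-readout circuits: fixed amplitude, 10x basal sweep (the averaging
  # protocol under which their mean shift is visible); others: wide sweep of
  # both basal level and amplitude
  if (model_id == "TC") data.frame(a = c(0.5, 1.5), b = c(0.2, 0.6))
  else if (model_id %in% c("KR09", "HYB_XAI", "HYB_S2")) {
    data.frame(a = c(0.1, 1.0), b = c(0.1, 0.1))
  } else data.frame(a = c(0.2, 1.0), b = c(0.1, 0.9))
}

#' Compute the circuit-by-stimulus combination matrix by simulation
#'
#' For each canonical circuit instantiation, determines by simulation
#' whether it (i) adapts exactly to a linear ramp, (ii) maintains the period
#' mean of its output across a sweep of sinusoidal stimuli, and (iii)
#' maintains the spatial mean of its output in a static spatial gradient
#' (with the row's diffusible species).
#'
#' @param config Named list: \code{n} (spatial grid, default 96),
#'   \code{thresholds} (classification thresholds), \code{t_end_spatial}.
#' @return Data frame as [combination_rows()] but with computed verdicts and
#'   an \code{agrees} column; per-cell reports in
#'   \code{attr(x, "reports")}.
#' @export
build_combination_matrix <- function(config = list()) {
  n <- config$n %||% 96
  th <- config$thresholds %||% list()
  t_end_sp <- config$t_end_spatial %||% 400
  rows <- combination_rows()
  reports <- vector("list", nrow(rows))
  got <- rows[, c("ramp", "periodic", "spatial")]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    basal <- .basal_of(r$model_id)
    rr <- ramp_response(r$model_id, r$signal_site)
    ramp_exact <- rr$report$response_class == "exact" ||
      rr$report$precision < (th$eps_exact %||% 0.01)
    pm <- period_mean_sweep(r$model_id, r$signal_site,
                            sweep = .matrix_periodic_sweep(r$model_id))
    kd <- stats::setNames(r$kd, r$diffusible)
    # strong gradient (b = 0.9 a): maintaining circuits hold their mean at
    # any admissible amplitude, while non-maintaining ones (whose deviation
    # is second order in the amplitude) show it clearly
    sg_a <- if (r$model_id == "TC") 0.5 else 1.0
    sg <- spatial_gradient_response(r$model_id, r$signal_site, kd,
                                    a = sg_a, b = 0.9 * sg_a, n = n,
                                    t_end = t_end_sp)
    sg$field <- NULL
    got$ramp[i] <- ramp_exact
    got$periodic[i] <- pm$maintained
    got$spatial[i] <- sg$maintained
    reports[[i]] <- list(ramp = rr$report, periodic = pm, spatial = sg)
  }
  out <- cbind(rows[, c("row", "model_id", "signal_site", "diffusible")],
               got,
               expected_ramp = rows$ramp, expected_periodic = rows$periodic,
               expected_spatial = rows$spatial)
  out$agrees <- out$ramp == out$expected_ramp &
    out$periodic == out$expected_periodic &
    out$spatial == out$expected_spatial
  attr(out, "reports") <- stats::setNames(reports, rows$row)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- full suite ------------------------------------------------------------

#' Run the full experiment suite
#'
#' Executes every registered experiment plus the combination matrix, and
#' optionally writes CSV and JSON reports.
#'
#' @param config Named list: \code{experiments} (names to run; default all),
#'   \code{matrix} (logical, run the combination matrix), \code{out_dir}
#'   (write reports there when non-NULL), \code{matrix_config}.
#' @return A \code{suite_report} list with \code{experiments} (per-experiment
#'   reports), \code{matrix}, \code{summary} data frame and \code{all_pass}.
#' @export
run_full_suite <- function(config = list()) {
  names_ <- config$experiments %||% list_experiments()
  reports <- lapply(names_, run_experiment)
  names(reports) <- names_
  mat <- if (config$matrix %||% TRUE) {
    build_combination_matrix(config$matrix_config %||% list())
  } else NULL
  summary <- data.frame(
    experiment = names_,
    pass = vapply(reports, function(r) isTRUE(r$pass), logical(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(mat)) {
    summary <- rbind(summary, data.frame(
      experiment = paste0("matrix_", mat$row), pass = mat$agrees))
  }
  out <- structure(list(experiments = reports, matrix = mat,
                        summary = summary,
                        all_pass = all(summary$pass)),
                   class = "suite_report")
  if (!is.null(config$out_dir)) generate_report(out, config$out_dir)
  out
}

#' @export
print.suite_report <- function(x, ...) {
  cat("<suite_report> ", sum(x$summary$pass), "/", nrow(x$summary),
      " checks pass\n", sep = "")
  fails <- x$summary$experiment[!x$summary$pass]
  if (length(fails)) cat("  failing:", paste(fails, collapse = ", "), "\n")
  invisible(x)
}

#' Write suite reports to disk
#'
#' Writes \code{summary.csv} (one row per experiment/metric),
#' \code{matrix.csv} (the combination matrix) and \code{suite.json} (full
#' machine-readable report) into \code{out_dir}.
#'
#' @param suite A \code{suite_report}.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
generate_report <- function(suite, out_dir) {
  stopifnot(inherits(suite, "suite_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(out_dir, "summary.csv")
  write.csv(suite$summary, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(suite$matrix)) {
    p <- file.path(out_dir, "matrix.csv")
    write.csv(suite$matrix, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "suite.json")
  slim <- suite
  slim$experiments <- lapply(slim$experiments, function(r) {
    r[!vapply(r, function(v)
      inherits(v, c("trajectory", "stf_field")), logical(1))]
  })
  jsonlite::write_json(slim, p, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
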