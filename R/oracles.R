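# ---------------------------------------------------------------------------
# Closed-form predictions: steady states, maintained means, ramp taxonomy.
#
# These are pure functions of the parameter set (plus stimulus slope or
# exponent where relevant) and serve as the independent acceptance surface
# for the simulator.  The underlying balances:
#   two-node inflow-outflow:    d(A+B)/dt   = k0 - k2 B
#   three-node, one outflow:    d(A+B+C)/dt = k0 + k3 - k2 B
#   three-node, two outflows:   d(A+B+C)/dt = k0 - k2 B - k33 C
#   transcritical:              d(ln C)/dt  = k3_tc B - k4   (C > 0)
#   feedforward readout:        R* -> RT r / (kr/kf + r), r = A/I
# ---------------------------------------------------------------------------

.params_of <- function(model_or_params, model_id = NULL) {
  if (inherits(model_or_params, "circuit_model")) {
    list(p = as.list(model_or_params$params), id = model_or_params$model_id,
         site = model_or_params$signal_site)
  } else {
    stopifnot(!is.null(model_id))
    entry <- .get_entry(model_id)
    p <- as.list(entry$params)
    ov <- as.list(model_or_params)
    p[names(ov)] <- ov
    list(p = p, id = model_id, site = NULL)
  }
}

#' Predicted steady state after a step stimulus
#'
#' Analytic steady-state levels of all species for a constant signal S.
#' The adapting output is signal-independent: \code{B = k0/k2} for the
#' two-node motif, \code{B = (k0+k3)/k2} for the one-outflow three-node
#' motif, \code{B = k4/k3_tc} (nonzero-C branch) for the transcritical
#' circuit, and \code{R* = RT r/(kr/kf + r)} with
#' \code{r = ka k_minus_i/(ki k_minus_a)} for the feedforward motif.
#'
#' @param model_id Circuit id (or a \code{circuit_model} as first argument).
#' @param params Named parameter overrides on the registry defaults.
#' @param S Constant signal level.
#' @return Named vector of steady-state concentrations.
#' @export
predict_step_steady_state <- function(model_id, params = list(), S = 1) {
  pp <- .params_of(params, if (is.character(model_id)) model_id else NULL)
  if (inherits(model_id, "circuit_model")) pp <- .params_of(model_id)
  p <- pp$p
  switch(pp$id,
    DR08_M1_IRREV = ,
    DR08_M1_REV = {
      B <- p$k0 / p$k2
      A <- (p$k11 + p$k2) * B / (p$k1 * S)
      c(A = A, B = B)
    },
    DR08_M32 = {
      # B/C proportionality: C = k32 B / (k31 + k33); total balance fixes B
      B <- p$k0 * (p$k31 + p$k33) /
        (p$k2 * (p$k31 + p$k33) + p$k33 * p$k32)
      C <- p$k32 * B / (p$k31 + p$k33)
      A <- ((p$k11 + p$k2 + p$k32) * B) / (p$k1 * S)
      c(A = A, B = B, C = C)
    },
    DR08_M34 = {
      B <- (p$k0 + p$k3) / p$k2
      C <- (p$k32 * B + p$k3) / p$k31
      A <- (p$k11 + p$k2 + p$k32) * B / (p$k1 * S)
      c(A = A, B = B, C = C)
    },
    TC = {
      B <- p$k4 / p$k3_tc
      A <- p$k2 * p$k4 / (p$k3_tc * p$k1 * S)
      C <- p$Xt - A - B
      if (C <= 0) {
        stop("TC infeasible at S = ", S,
             ": nonzero-C branch does not exist (Xt too small)",
             call. = FALSE)
      }
      c(A = A, B = B, C = C)
    },
    KR09 = {
      A <- p$ka * S / p$k_minus_a
      I <- p$ki * S / p$k_minus_i
      r <- p$ka * p$k_minus_i / (p$ki * p$k_minus_a)
      c(A = A, I = I, Rstar = p$RT * r / (p$kr / p$kf + r))
    },
    HYB_XAI = {
      A <- p$ka * S / p$k_minus_a
      I <- p$ki * S / p$k_minus_i
      c(X = p$k0_h * A / (p$k2_h * I), A = A, I = I)
    },
    HYB_S2 = ,
    HYB_AUTO = {
      A <- p$ka * S / p$k_minus_a
      I <- p$ki * S / p$k_minus_i
      X2 <- p$k0_h * A / (p$k2_h * I)
      if (pp$id == "HYB_S2") {
        X1 <- (p$k11_h * S^2 + p$k2_h * I) * X2 / p$k1_h
      } else {
        # k1 X1 = k11 X1 X2 + k2 I X2  =>  X1 (k1 - k11 X2) = k2 I X2
        X1 <- p$k2_h * I * X2 / (p$k1_h - p$k11_h * X2)
        if (!is.finite(X1) || X1 < 0) {
          stop("HYB_AUTO has no positive steady state at S = ", S,
               call. = FALSE)
        }
      }
      c(X1 = X1, X2 = X2, A = A, I = I)
    },
    stop("no closed-form steady state for ", pp$id, call. = FALSE)
  )
}

#' Predicted period mean of the output under a periodic stimulus
#'
#' Constant-coefficient integral balances fix the time average of the
#' output over one stimulus cycle, independent of the stimulus basal level
#' and amplitude, for the inflow-outflow motifs (signal on the A-B
#' interconversion) and the transcritical circuit. The feedforward and
#' hybrid circuits, and disallowed signal sites, do not maintain the mean.
#'
#' @param model_id Circuit id.
#' @param signal_site Signal site.
#' @param params Named parameter overrides.
#' @return The predicted mean, or \code{NA_real_} when the mean is not
#'   maintained for that combination.
#' @export
predict_period_mean <- function(model_id, signal_site, params = list()) {
  p <- .params_of(params, model_id)$p
  ok_ab <- signal_site %in% c("A_to_B", "B_to_A")
  switch(model_id,
    DR08_M1_IRREV = ,
    DR08_M1_REV = if (ok_ab) p$k0 / p$k2 else NA_real_,
    DR08_M34 = if (ok_ab) (p$k0 + p$k3) / p$k2 else NA_real_,
    DR08_M32 = if (ok_ab) {
      p$k0 * (p$k31 + p$k33) / (p$k2 * (p$k31 + p$k33) + p$k33 * p$k32)
    } else NA_real_,
    TC = if (ok_ab) p$k4 / p$k3_tc else NA_real_,
    NA_real_
  )
}

#' Predicted spatial mean of the output in a static spatial stimulus
#'
#' At steady state on a periodic domain the diffusion term integrates to
#' zero, so the same integral balances that fix temporal means fix the
#' spatial mean of the output - provided the signal does not enter the
#' balance (inflow-outflow motifs with signal on the A-B interconversion;
#' for the two-outflow motif additionally the signal must not touch the C
#' transitions). The hybrid circuits maintain
#' \code{<X> = (k0_h/k2_h)(ka k_minus_i/(k_minus_a ki))} via the
#' homogenising diffusible inhibitor leg. The transcritical circuit does
#' not maintain its spatial mean (a diffusible A forces the C = 0 branch).
#'
#' @param model_id Circuit id.
#' @param diffusible Character vector of diffusing species (affects which
#'   combinations maintain the mean).
#' @param signal_site Signal site.
#' @param params Named parameter overrides.
#' @return Predicted spatial mean, or \code{NA_real_} when not maintained.
#' @export
predict_spatial_mean <- function(model_id, diffusible = character(),
                                 signal_site = "A_to_B", params = list()) {
  p <- .params_of(params, model_id)$p
  ok_ab <- signal_site %in% c("A_to_B", "B_to_A")
  switch(model_id,
    DR08_M1_IRREV = ,
    DR08_M1_REV = if (ok_ab) p$k0 / p$k2 else NA_real_,
    DR08_M34 = if (ok_ab) (p$k0 + p$k3) / p$k2 else NA_real_,
    DR08_M32 = if (ok_ab && !("C" %in% diffusible)) {
      p$k0 * (p$k31 + p$k33) / (p$k2 * (p$k31 + p$k33) + p$k33 * p$k32)
    } else NA_real_,
    TC = NA_real_,
    KR09 = NA_real_,
    HYB_XAI = ,
    HYB_S2 = ,
    HYB_AUTO = (p$k0_h / p$k2_h) *
      (p$ka * p$k_minus_i) / (p$k_minus_a * p$ki),
    NA_real_
  )
}

# rule table: which (circuit, site, ramp kind) combinations adapt exactly
#' Predicted response class for a ramp stimulus
#'
#' Encodes the structural rules for exact adaptation in increasing stimuli:
#' inflow-outflow motifs adapt as long as the ramp does not act on the
#' conversion/degradation of the output species (for the two-outflow motif
#' only the A-to-B site adapts; for the fully reversible two-outflow motif
#' no site adapts); the transcritical circuit adapts to linear, quadratic
#' and exponential signals through the A-to-B site; the feedforward motif
#' adapts to linear and quadratic ramps but not to exponentials.
#'
#' @param model_id Circuit id.
#' @param signal_site Signal site.
#' @param ramp_kind One of \code{"linear_ramp"}, \code{"quadratic_ramp"},
#'   \code{"exponential"}.
#' @param params Named parameter overrides (used for limit values).
#' @return List with \code{class} (\code{"exact"} or \code{"not_exact"}) and
#'   \code{limit} (predicted output limit where known: the adapted level for
#'   exact cases, 0 for the reverse-site quadratic ramp, else \code{NA}).
#' @export
predict_ramp_class <- function(model_id, signal_site,
                               ramp_kind = "linear_ramp", params = list()) {
  p <- .params_of(params, model_id)$p
  exact <- function(limit) list(class = "exact", limit = limit)
  inexact <- function(limit = NA_real_) list(class = "not_exact",
                                             limit = limit)
  switch(model_id,
    DR08_M1_IRREV = ,
    DR08_M1_REV = {
      if (signal_site == "A_to_B") exact(p$k0 / p$k2)
      else if (signal_site == "B_to_A") {
        if (ramp_kind == "quadratic_ramp") inexact(0) else inexact()
      } else inexact()
    },
    DR08_M32 = {
      if (signal_site == "A_to_B") {
        exact(p$k0 * (p$k31 + p$k33) /
                (p$k2 * (p$k31 + p$k33) + p$k33 * p$k32))
      } else inexact()
    },
    DR08_M34 = {
      if (signal_site %in% c("A_to_B", "C_to_A")) {
        exact((p$k0 + p$k3) / p$k2)
      } else if (signal_site == "B_to_A" &&
                 ramp_kind == "quadratic_ramp") inexact(0)
      else inexact()
    },
    REV3 = {
      if (p$k33 > 0) inexact()  # two outflows, fully reversible: never exact
      else if (signal_site %in% c("B_to_A", "B_to_C")) inexact()
      else exact(p$k0 / p$k2)
    },
    TC = {
      if (signal_site == "A_to_B") exact(p$k4 / p$k3_tc) else inexact()
    },
    KR09 = {
      if (ramp_kind %in% c("linear_ramp", "quadratic_ramp")) {
        r <- p$ka * p$k_minus_i / (p$ki * p$k_minus_a)
        exact(p$RT * r / (p$kr / p$kf + r))
      } else inexact()
    },
    HYB_XAI = exact((p$k0_h / p$k2_h) *
                      (p$ka * p$k_minus_i) / (p$k_minus_a * p$ki)),
    HYB_S2 = inexact(),
    # with the inhibitor-mediated outflow retained (required for the
    # spatial-mean property) the subcritical autocatalytic augmentation
    # stays slaved to the growing legs and the ratio cancellation survives,
    # so the output still adapts exactly in ramps
    HYB_AUTO = exact((p$k0_h / p$k2_h) *
                       (p$ka * p$k_minus_i) / (p$k_minus_a * p$ki)),
    stop("unknown combination", call. = FALSE)
  )
}

#' Limiting activator/inhibitor ratio under an exponential stimulus
#'
#' Under \code{S = S0 exp(lambda t)} both feedforward legs grow
#' exponentially and their ratio asymptotes to
#' \code{r(lambda) = ka (k_minus_i + lambda) / (ki (k_minus_a + lambda))},
#' which differs from the prestimulus ratio unless the two legs decay at the
#' same rate; the readout settles at \code{RT r/(kr/kf + r)}.
#'
#' @param params Named KR09 parameter overrides.
#' @param lambda Exponent of the stimulus (> 0; the limit lambda -> 0
#'   recovers the prestimulus ratio).
#' @return List with \code{ratio} (limiting A/I) and \code{Rstar} (limiting
#'   readout level).
#' @export
kr09_exponential_ratio <- function(params = list(), lambda) {
  p <- .params_of(params, "KR09")$p
  r <- p$ka * (p$k_minus_i + lambda) / (p$ki * (p$k_minus_a + lambda))
  list(ratio = r, Rstar = p$RT * r / (p$kr / p$kf + r))
}

#' Asymptotic growth rate of A under a reverse-site linear ramp
#'
#' When the ramp acts on the B-to-A conversion of the two-node motif, B
#' settles at a non-adaptive quasi-steady level while A grows linearly; the
#' asymptotic ODE \code{dA/dt = k0 - (k1 k2/(k11 S1)) A/t} has the linear
#' solution with slope \code{k0 / (1 + k1 k2/(k11 S1))}.
#'
#' @param params Named overrides on the reversible two-node motif defaults.
#' @param S1 Ramp slope (> 0).
#' @return Predicted asymptotic dA/dt.
#' @export
two_node_reverse_ramp_slope <- function(params = list(), S1) {
  p <- .params_of(params, "DR08_M1_REV")$p
  if (p$k11 <= 0) stop("reverse site absent (k11 = 0)", call. = FALSE)
  if (S1 <= 0) stop("S1 must be positive", call. = FALSE)
  p$k0 / (1 + p$k1 * p$k2 / (p$k11 * S1))
}
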