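# ---------------------------------------------------------------------------
# Time integration of circuit models, well-mixed and on a 1-D periodic domain.
#
# Protocol: the model is first equilibrated at the basal signal level; the
# equilibrated state is the initial condition and the clock restarts at 0, so
# the pre-onset segment (t < t0) of every trajectory sits at the basal steady
# state.  Integration uses stiff-capable variable-step solvers from deSolve
# (lsoda for the ODE case, lsodes with automatically detected sparsity for
# the method-of-lines case, where diffusion makes the system stiff).
# ---------------------------------------------------------------------------

.default_settings <- function() {
  list(rtol = 1e-8, atol = 1e-10, steady_tol = 1e-6, window = 0.1,
       equil_tmax = 1e4, equil_chunk = 50, equil_tol = 1e-10)
}

.merge_settings <- function(settings) {
  s <- .default_settings()
  if (length(settings)) s[names(settings)] <- settings
  s
}

# Equilibrate a model at constant signal S; returns named steady state.
.equilibrate <- function(model, S, settings = list()) {
  s <- .merge_settings(settings)
  y <- .initial_guess(model, S)
  f <- function(t, y, parms) {
    list(unlist(model$rhs(stats::setNames(as.list(y), model$species), S)))
  }
  t_done <- 0
  repeat {
    resid <- max(abs(f(0, y, NULL)[[1]]) / pmax(abs(y), 1e-8))
    if (resid < s$equil_tol) break
    if (t_done >= s$equil_tmax) {
      stop("pre-equilibration failed: no basal steady state within t = ",
           s$equil_tmax, " (model ", model$model_id, ", residual ",
           signif(resid, 3), ")", call. = FALSE)
    }
    out <- deSolve::ode(y = y, times = c(0, s$equil_chunk), func = f,
                        parms = NULL, method = "lsoda",
                        rtol = s$rtol, atol = s$atol)
    y <- stats::setNames(as.numeric(out[nrow(out), -1]), model$species)
    t_done <- t_done + s$equil_chunk
  }
  y
}

#' Integrate a circuit forward in time (well-mixed)
#'
#' Pre-equilibrates the circuit at the stimulus's basal level, then
#' integrates the ODE system on \code{[0, t_end]} with the signal evaluated
#' from the stimulus specification. Uses a stiff-capable variable-step
#' integrator (lsoda) at tight tolerances, as the exact-adaptation
#' diagnostics require precision well below the classification threshold.
#'
#' @param model A \code{circuit_model} from [build_circuit()].
#' @param stim A temporal \code{stimulus}.
#' @param t_end Final time (the stimulus onset \code{t0} should lie inside
#'   \code{[0, t_end]}). Default: onset + 1000.
#' @param times Optional explicit output time grid overriding \code{t_end}.
#' @param n_out Number of output points when \code{times} is not given.
#' @param settings Named list overriding solver settings
#'   (\code{rtol}, \code{atol}, \code{steady_tol}, \code{window}, ...).
#' @return A \code{trajectory} object: list with \code{times} (increasing),
#'   \code{conc} (times x species matrix), \code{model}, \code{stim},
#'   \code{status} (\code{"completed"} or \code{"diverged"}) and solver
#'   metadata.
#' @export
integrate_temporal <- function(model, stim, t_end = NULL, times = NULL,
                               n_out = 2000, settings = list()) {
  stopifnot(inherits(model, "circuit_model"), inherits(stim, "stimulus"))
  if (is_spatial_stimulus(stim)) {
    stop("spatial stimulus requires integrate_spatial()", call. = FALSE)
  }
  s <- .merge_settings(settings)
  if (is.null(times)) {
    if (is.null(t_end)) t_end <- stim$t0 + 1000
    times <- seq(0, t_end, length.out = n_out + 1L)
  }
  y0 <- .equilibrate(model, stim$a, s)
  f <- function(t, y, parms) {
    S <- evaluate_stimulus(stim, t)
    list(unlist(model$rhs(stats::setNames(as.list(y), model$species), S)))
  }
  out <- suppressWarnings(
    deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                 method = "lsoda", rtol = s$rtol, atol = s$atol)
  )
  conc <- unname(as.matrix(out[, -1, drop = FALSE]))
  colnames(conc) <- model$species
  completed <- nrow(conc) == length(times) && all(is.finite(conc))
  structure(list(
    times = times[seq_len(nrow(conc))], conc = conc, model = model,
    stim = stim, status = if (completed) "completed" else "diverged",
    settings = s, basal_state = y0
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$model$model_id, " under ", x$stim$kind,
      " stimulus; t in [", min(x$times), ", ", max(x$times), "], ",
      length(x$times), " points, status ", x$status, "\n", sep = "")
  invisible(x)
}

# second-difference operator on a periodic grid, as index shifts
.periodic_lap <- function(v, dx2) {
  n <- length(v)
  (v[c(2:n, 1L)] - 2 * v + v[c(n, 1:(n - 1L))]) / dx2
}

#' Integrate a circuit on a 1-D periodic domain (method of lines)
#'
#' Discretizes the reaction-diffusion system on \code{n} uniform grid points
#' over a periodic domain of length \code{L} (taken from the stimulus for
#' spatial kinds), with second-order central differences for the diffusion
#' of species with nonzero diffusivity, and integrates the coupled ODE
#' system with lsodes (sparse stiff solver).
#'
#' @param model A \code{circuit_model} (per-species diffusivities from
#'   [build_circuit()]).
#' @param stim A \code{stimulus}; spatial or purely temporal (the latter is
#'   applied uniformly).
#' @param n Number of grid points (>= 16).
#' @param t_end Final time; default onset + 200.
#' @param times Optional explicit output time grid.
#' @param n_out Number of output times when \code{times} is not given.
#' @param settings Solver settings as in [integrate_temporal()].
#' @return An \code{stf_field} object: list with \code{times},
#'   \code{positions}, \code{conc} (array times x positions x species),
#'   \code{model}, \code{stim}, \code{status}.
#' @export
integrate_spatial <- function(model, stim, n = 128, t_end = NULL,
                              times = NULL, n_out = 400, settings = list()) {
  stopifnot(inherits(model, "circuit_model"), inherits(stim, "stimulus"))
  if (n < 16) stop("grid too coarse: n must be >= 16", call. = FALSE)
  s <- .merge_settings(settings)
  L <- if (is_spatial_stimulus(stim)) stim$L else 1
  theta <- seq(0, L, length.out = n + 1L)[seq_len(n)]
  dx2 <- (L / n)^2
  if (is.null(times)) {
    if (is.null(t_end)) t_end <- stim$t0 + 200
    times <- seq(0, t_end, length.out = n_out + 1L)
  }
  nsp <- length(model$species)
  kd <- model$diffusivities
  eq <- .equilibrate(model, stim$a, s)
  y0 <- rep(eq, each = n)
  f <- function(t, y, parms) {
    mat <- matrix(y, nrow = n, ncol = nsp)
    x <- stats::setNames(lapply(seq_len(nsp), function(j) mat[, j]),
                         model$species)
    S <- .stim_profile(stim, t, theta)
    d <- model$rhs(x, S)
    dv <- numeric(n * nsp)
    for (j in seq_len(nsp)) {
      dj <- d[[model$species[j]]]
      if (kd[j] > 0) dj <- dj + kd[j] * .periodic_lap(mat[, j], dx2)
      dv[((j - 1L) * n + 1L):(j * n)] <- dj
    }
    list(dv)
  }
  out <- suppressWarnings(
    deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                 method = "lsodes", rtol = s$rtol, atol = s$atol)
  )
  nt <- nrow(out)
  conc <- array(as.matrix(out[, -1, drop = FALSE]),
                dim = c(nt, n, nsp),
                dimnames = list(NULL, NULL, model$species))
  completed <- nt == length(times) && all(is.finite(conc))
  structure(list(
    times = times[seq_len(nt)], positions = theta, conc = conc,
    model = model, stim = stim,
    status = if (completed) "completed" else "diverged",
    settings = s, basal_state = eq
  ), class = "stf_field")
}

#' @export
print.stf_field <- function(x, ...) {
  cat("<stf_field> ", x$model$model_id, " under ", x$stim$kind,
      " stimulus; ", length(x$positions), " grid points, t in [",
      min(x$times), ", ", max(x$times), "], status ", x$status, "\n",
      sep = "")
  invisible(x)
}

#' Detect a steady state (and classify growth) on a trailing window
#'
#' A species is steady when the scaled derivative criterion
#' \code{max |dy/dt| * T_window / max(|y|, atol)} falls below \code{tol}
#' over the trailing window. When not steady, the trailing segment is
#' classified by the slope of a log-log regression of \code{y} against
#' \code{t}: slope in \code{[0.8, 1.2]} is linear growth, above 1.2
#' superlinear, otherwise bounded (e.g. oscillatory).
#'
#' @param traj A \code{trajectory}.
#' @param species Species name (default: the model's output species).
#' @param window Trailing fraction of the time span to analyse.
#' @param tol Steadiness tolerance.
#' @return List with \code{steady} (logical), \code{value} (trailing value if
#'   steady, else \code{NA}), \code{growth_class} (\code{"bounded"},
#'   \code{"linear_growth"} or \code{"superlinear"}), \code{slope} (log-log
#'   slope), and \code{rate} (trailing linear growth rate dy/dt).
#' @export
detect_steady_state <- function(traj, species = NULL, window = 0.1,
                                tol = 1e-6) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(species)) species <- traj$model$output
  y <- traj$conc[, species]
  t <- traj$times
  t_win <- max(t) - window * (max(t) - min(t))
  if (t_win <= min(t)) stop("window longer than trajectory", call. = FALSE)
  idx <- which(t >= t_win)
  if (length(idx) < 5L) stop("window contains too few points", call. = FALSE)
  tw <- t[idx]; yw <- y[idx]
  dydt <- diff(yw) / diff(tw)
  span <- max(tw) - min(tw)
  crit <- max(abs(dydt)) * span / max(abs(mean(yw)), 1e-10)
  if (crit < tol) {
    return(list(steady = TRUE, value = yw[length(yw)],
                growth_class = "bounded", slope = 0,
                rate = mean(dydt)))
  }
  pos <- yw > 0 & tw > 0
  slope <- if (sum(pos) >= 5L) {
    unname(coef(lm(log(yw[pos]) ~ log(tw[pos])))[2L])
  } else 0
  growth <- if (slope > 1.2) "superlinear"
            else if (slope >= 0.8) "linear_growth"
            else "bounded"
  list(steady = FALSE, value = NA_real_, growth_class = growth,
       slope = slope, rate = mean(dydt[seq(max(1, length(dydt) - 20),
                                           length(dydt))]))
}
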