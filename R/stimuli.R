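# ---------------------------------------------------------------------------
# Parametric space-time stimulus families S(theta, t) >= 0.
#
# All families equal the basal level a for t < t0.  Spatial families are
# L-periodic in theta; (t - t0)+ denotes the positive part.
#   step:            S = a (t < t0), a + b (t >= t0)
#   linear_ramp:     S = a + S1 * (t - t0)+
#   quadratic_ramp:  S = a + S1 * (t - t0)+^2
#   capped_ramp:     S = min(a + S1 * (t - t0)+, Smax)
#   exponential:     S = a * exp(lambda * (t - t0)+)
#   sinusoid:        S = a + b * sin(w * (t - t0)+)
#   static_gradient: S = a                  (t < t0)
#                        a + b*sin(2 pi m theta / L)             (t >= t0)
#   spatial_ramp:    S = a + S1 * (1 + eps*sin(2 pi m theta/L)) * (t - t0)+
#   travelling_wave: S = a + b * sin(2 pi m theta / L - w (t - t0)+)
#   standing_wave:   S = a + b * sin(2 pi m theta / L) * sin(w (t - t0)+)
# ---------------------------------------------------------------------------

.stim_kinds <- c("step", "linear_ramp", "capped_ramp", "quadratic_ramp",
                 "exponential", "sinusoid", "static_gradient", "spatial_ramp",
                 "travelling_wave", "standing_wave")
.spatial_kinds <- c("static_gradient", "spatial_ramp", "travelling_wave",
                    "standing_wave")
.periodic_kinds <- c("sinusoid", "travelling_wave", "standing_wave")

#' Construct a stimulus specification
#'
#' A stimulus is a nonnegative space-time signal S(theta, t) from one of ten
#' parametric families. Every family holds the basal level \code{a} for
#' \code{t < t0}; spatial families are periodic over a domain of length
#' \code{L}.
#'
#' @param kind One of \code{"step"}, \code{"linear_ramp"},
#'   \code{"capped_ramp"}, \code{"quadratic_ramp"}, \code{"exponential"},
#'   \code{"sinusoid"}, \code{"static_gradient"}, \code{"spatial_ramp"},
#'   \code{"travelling_wave"}, \code{"standing_wave"}.
#' @param a Basal level (concentration-equivalent, >= 0).
#' @param t0 Onset time.
#' @param S1 Ramp slope (linear/quadratic/spatial ramps).
#' @param Smax Cap level (capped ramp).
#' @param lambda Exponent (exponential stimulus).
#' @param b Amplitude: step size, sinusoid/wave amplitude, or gradient
#'   amplitude of the static gradient.
#' @param w Angular frequency (sinusoid and waves); the period is 2*pi/w.
#' @param m Integer spatial mode (number of wavelengths across the domain).
#' @param eps Relative spatial modulation of the ramp slope (spatial_ramp,
#'   must satisfy |eps| <= 1 for positivity).
#' @param L Domain length (spatial kinds).
#' @return An object of class \code{stimulus}.
#' @export
stimulus <- function(kind, a = 0.1, t0 = 50, S1 = 0.1, Smax = 2,
                     lambda = 0.1, b = 0.05, w = 1, m = 1, eps = 0.5, L = 1) {
  kind <- match.arg(kind, .stim_kinds)
  spec <- structure(list(kind = kind, a = a, t0 = t0, S1 = S1, Smax = Smax,
                         lambda = lambda, b = b, w = w, m = as.integer(m),
                         eps = eps, L = L),
                    class = "stimulus")
  stopifnot(a >= 0, L > 0)
  v <- validate_positivity(spec)
  if (!isTRUE(v)) stop("stimulus can become negative: ", v, call. = FALSE)
  spec
}

#' @export
print.stimulus <- function(x, ...) {
  flds <- switch(x$kind,
    step = c("a", "b", "t0"),
    linear_ramp = c("a", "S1", "t0"),
    capped_ramp = c("a", "S1", "Smax", "t0"),
    quadratic_ramp = c("a", "S1", "t0"),
    exponential = c("a", "lambda", "t0"),
    sinusoid = c("a", "b", "w", "t0"),
    static_gradient = c("a", "b", "m", "L", "t0"),
    spatial_ramp = c("a", "S1", "eps", "m", "L", "t0"),
    c("a", "b", "w", "m", "L", "t0"))
  cat("<stimulus> ", x$kind, ": ",
      paste(flds, signif(unlist(x[flds]), 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Is a stimulus kind spatial?
#' @param spec A \code{stimulus}.
#' @return Logical.
#' @export
is_spatial_stimulus <- function(spec) spec$kind %in% .spatial_kinds

#' Evaluate a stimulus
#'
#' Closed-form evaluation of S(theta, t). The position argument is required
#' for spatial kinds and rejected for purely temporal kinds.
#'
#' @param spec A \code{stimulus}.
#' @param t Time (scalar or vector).
#' @param theta Position in \code{[0, L)}; may be a vector (for a scalar
#'   \code{t}) giving the signal profile across the domain.
#' @return Nonnegative signal value(s).
#' @export
evaluate_stimulus <- function(spec, t, theta = NULL) {
  stopifnot(inherits(spec, "stimulus"))
  spatial <- is_spatial_stimulus(spec)
  if (spatial && is.null(theta)) {
    stop("spatial stimulus '", spec$kind, "' requires a position theta",
         call. = FALSE)
  }
  if (!spatial && !is.null(theta)) {
    stop("temporal stimulus '", spec$kind, "' takes no position argument",
         call. = FALSE)
  }
  if (spatial && (any(theta < 0) || any(theta >= spec$L))) {
    stop("theta must lie in [0, L)", call. = FALSE)
  }
  tau <- pmax(t - spec$t0, 0)
  on <- as.numeric(t >= spec$t0)
  phase <- if (spatial) 2 * pi * spec$m * theta / spec$L else NULL
  with(spec, switch(kind,
    step = a + b * on,
    linear_ramp = a + S1 * tau,
    quadratic_ramp = a + S1 * tau^2,
    capped_ramp = pmin(a + S1 * tau, pmax(Smax, a)),
    exponential = a * exp(lambda * tau),
    sinusoid = a + b * sin(w * tau) * on,
    static_gradient = a + b * sin(phase) * on,
    spatial_ramp = a + S1 * (1 + eps * sin(phase)) * tau,
    travelling_wave = a + b * sin(phase - w * tau) * on,
    standing_wave = a + b * sin(phase) * sin(w * tau) * on
  ))
}

#' Period of a stimulus
#'
#' @param spec A \code{stimulus}.
#' @return The period \code{2*pi/w} for the sinusoid and the travelling and
#'   standing waves; \code{NULL} for aperiodic kinds.
#' @export
stimulus_period <- function(spec) {
  stopifnot(inherits(spec, "stimulus"))
  if (spec$kind %in% .periodic_kinds) 2 * pi / spec$w else NULL
}

#' Check that a stimulus stays nonnegative
#'
#' Verifies analytically that the minimum of S over all (theta, t) is
#' nonnegative: oscillatory kinds require \code{|b| <= a}, the spatially
#' modulated ramp requires \code{|eps| <= 1}, the step requires
#' \code{a + b >= 0}.
#'
#' @param spec A \code{stimulus}.
#' @return \code{TRUE} if the signal is nonnegative everywhere, otherwise a
#'   character description of the violation.
#' @export
validate_positivity <- function(spec) {
  stopifnot(inherits(spec, "stimulus"))
  bad <- function(msg, minv) sprintf("%s (analytic minimum %g < 0)", msg, minv)
  with(spec, switch(kind,
    step = if (a + b >= 0) TRUE else bad("step to a negative level", a + b),
    sinusoid = ,
    travelling_wave = ,
    standing_wave = if (abs(b) <= a) TRUE else
      bad(sprintf("amplitude b = %g exceeds basal a = %g", b, a), a - abs(b)),
    static_gradient = if (abs(b) <= a) TRUE else
      bad(sprintf("gradient amplitude b = %g exceeds basal a = %g", b, a),
          a - abs(b)),
    spatial_ramp = if (abs(eps) <= 1 && S1 >= 0) TRUE else
      bad("spatial slope modulation |eps| > 1 or negative slope",
          min(S1 * (1 - abs(eps)), S1)),
    linear_ramp = ,
    quadratic_ramp = if (S1 >= 0) TRUE else bad("negative ramp slope", -Inf),
    capped_ramp = if (S1 >= 0 && Smax >= 0) TRUE else
      bad("negative slope or cap", min(S1, Smax)),
    exponential = TRUE
  ))
}

# Signal profile over a spatial grid at one time; temporal stimuli broadcast.
.stim_profile <- function(spec, t, theta) {
  if (is_spatial_stimulus(spec)) evaluate_stimulus(spec, t, theta)
  else rep(evaluate_stimulus(spec, t), length(theta))
}
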