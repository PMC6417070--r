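# ---------------------------------------------------------------------------
# Response taxonomy and mean-value diagnostics.
#
# Precision of adaptation: P = |y_ss - y_base| / max(|y_peak - y_base|, delta)
# with classes
#   exact              P <  eps_exact              (default 0.01)
#   partial            eps_exact <= P < 0.5
#   nonadaptive_steady P >= 0.5 and trajectory bounded
#   unbounded          trailing growth (linear or faster) in the output
# The bands separate every in-scope case by at least an order of magnitude.
# ---------------------------------------------------------------------------

.default_thresholds <- function() {
  list(eps_exact = 0.01, partial_max = 0.5, delta = 1e-12)
}

#' Classify the response of an output species
#'
#' Compares the trailing (steady or quasi-steady) value of the output to its
#' pre-onset baseline, scaled by the peak deviation, and assigns one of the
#' four response classes: \code{exact}, \code{partial},
#' \code{nonadaptive_steady}, \code{unbounded}.
#'
#' @param traj A \code{trajectory} with a pre-onset segment (t < t0).
#' @param species Output species (default: the model's output).
#' @param thresholds Named list overriding \code{eps_exact} (exact band),
#'   \code{partial_max}, \code{delta} (guard for zero peak deviation).
#' @return A \code{response_report}: list with \code{response_class},
#'   \code{precision}, \code{baseline}, \code{steady_value},
#'   \code{peak_deviation}, \code{growth_class}, \code{thresholds}.
#' @export
classify_response <- function(traj, species = NULL, thresholds = list()) {
  stopifnot(inherits(traj, "trajectory"))
  if (!identical(traj$status, "completed")) {
    stop("trajectory did not complete", call. = FALSE)
  }
  th <- .default_thresholds()
  th[names(thresholds)] <- thresholds
  if (is.null(species)) species <- traj$model$output
  t0 <- traj$stim$t0
  pre <- traj$times < t0
  if (!any(pre)) stop("no pre-onset baseline (t0 <= 0)", call. = FALSE)
  y <- traj$conc[, species]
  baseline <- y[max(which(pre))]
  post <- traj$times >= t0
  peak_dev <- max(abs(y[post] - baseline))
  det <- detect_steady_state(traj, species)
  growing <- !det$steady && det$growth_class %in% c("linear_growth",
                                                    "superlinear")
  if (growing) {
    rep <- list(response_class = "unbounded", precision = Inf,
                baseline = baseline, steady_value = NA_real_,
                peak_deviation = peak_dev, growth_class = det$growth_class,
                thresholds = th)
    class(rep) <- "response_report"
    return(rep)
  }
  y_ss <- if (det$steady) det$value else y[length(y)]
  # no measurable excursion (e.g. a zero-size step): identity response
  noise_floor <- 1e-9 * max(abs(baseline), 1)
  P <- if (peak_dev <= max(th$delta, noise_floor)) 0
       else abs(y_ss - baseline) / peak_dev
  cls <- if (P < th$eps_exact) "exact"
         else if (P < th$partial_max) "partial"
         else "nonadaptive_steady"
  rep <- list(response_class = cls, precision = P, baseline = baseline,
              steady_value = y_ss, peak_deviation = peak_dev,
              growth_class = det$growth_class, thresholds = th)
  class(rep) <- "response_report"
  rep
}

#' @export
print.response_report <- function(x, ...) {
  cat("<response_report> class = ", x$response_class,
      sprintf(" (P = %.3g, baseline = %.4g, steady = %.4g, peak dev = %.3g)",
              x$precision, x$baseline, x$steady_value, x$peak_deviation),
      "\n", sep = "")
  invisible(x)
}

# Trapezoid mean of y(t) over [t1, t2] after interpolating on a uniform grid.
.cycle_mean <- function(t, y, t1, t2, n_sub = 256L) {
  g <- seq(t1, t2, length.out = n_sub + 1L)
  yi <- approx(t, y, xout = g, rule = 2)$y
  (sum(yi) - (yi[1L] + yi[n_sub + 1L]) / 2) / n_sub
}

#' Temporal period mean of the output under a periodic stimulus
#'
#' Computes per-cycle means of the output (cycles counted from the stimulus
#' onset), discards cycles until the cycle-to-cycle drift of the mean falls
#' below tolerance, and reports the mean over the last full cycle. For a
#' spatio-temporal field the mean is computed per location and the reported
#' scalar is the spatial average of the converged local means.
#'
#' @param traj A \code{trajectory} or \code{stf_field} covering several
#'   stimulus periods after onset.
#' @param period Stimulus period (default from [stimulus_period()]).
#' @param species Species (default: model output).
#' @param drift_tol Relative cycle-to-cycle drift below which the mean is
#'   considered converged.
#' @param max_cycles Cap on the number of cycles examined.
#' @return A \code{mean_report}: list with \code{mean} (converged period
#'   mean; spatial average of local means for fields), \code{local_means}
#'   (per-location means for fields), \code{drift}, \code{cycles_used},
#'   \code{converged}.
#' @export
temporal_period_mean <- function(traj, period = NULL, species = NULL,
                                 drift_tol = 1e-6, max_cycles = 200) {
  if (is.null(period)) period <- stimulus_period(traj$stim)
  if (is.null(period)) stop("stimulus is not periodic", call. = FALSE)
  if (is.null(species)) species <- traj$model$output
  t <- traj$times
  t0 <- traj$stim$t0
  n_cyc <- min(floor((max(t) - t0) / period), max_cycles)
  if (n_cyc < 2) stop("trajectory covers fewer than two stimulus periods",
                      call. = FALSE)
  get_series <- function(y) {
    means <- vapply(seq_len(n_cyc), function(k) {
      .cycle_mean(t, y, t0 + (k - 1) * period, t0 + k * period)
    }, numeric(1))
    means
  }
  if (inherits(traj, "trajectory")) {
    means <- get_series(traj$conc[, species])
    drift <- abs(diff(means)) / pmax(abs(means[-1]), 1e-12)
    converged <- drift[length(drift)] < drift_tol
    out <- list(mean = means[n_cyc], local_means = NULL,
                cycle_means = means, drift = drift[length(drift)],
                cycles_used = n_cyc, converged = converged)
  } else {
    y <- traj$conc[, , species]
    local <- vapply(seq_along(traj$positions), function(i) {
      .cycle_mean(t, y[, i], t0 + (n_cyc - 1) * period, t0 + n_cyc * period)
    }, numeric(1))
    prev <- vapply(seq_along(traj$positions), function(i) {
      .cycle_mean(t, y[, i], t0 + (n_cyc - 2) * period,
                  t0 + (n_cyc - 1) * period)
    }, numeric(1))
    drift <- max(abs(local - prev) / pmax(abs(local), 1e-12))
    out <- list(mean = mean(local), local_means = local, cycle_means = NULL,
                drift = drift, cycles_used = n_cyc,
                converged = drift < drift_tol)
  }
  class(out) <- "mean_report"
  out
}

#' @export
print.mean_report <- function(x, ...) {
  cat("<mean_report> mean = ", signif(x$mean, 6), " (", x$cycles_used,
      " cycles, drift = ", signif(x$drift, 3), ", converged = ",
      x$converged, ")\n", sep = "")
  invisible(x)
}

#' Spatial mean of a species at a given time
#'
#' Trapezoid-rule mean over the periodic grid (equal weights on a uniform
#' periodic grid).
#'
#' @param field An \code{stf_field}.
#' @param species Species (default: model output).
#' @param time Time at which to evaluate (default: final time).
#' @return Scalar spatial mean.
#' @export
spatial_mean <- function(field, species = NULL, time = NULL) {
  stopifnot(inherits(field, "stf_field"))
  if (is.null(species)) species <- field$model$output
  it <- if (is.null(time)) length(field$times)
        else which.min(abs(field$times - time))
  mean(field$conc[it, , species])
}

#' Spatial profile of a species at a given time
#'
#' @inheritParams spatial_mean
#' @return Numeric vector over the grid.
#' @export
spatial_profile <- function(field, species = NULL, time = NULL) {
  stopifnot(inherits(field, "stf_field"))
  if (is.null(species)) species <- field$model$output
  it <- if (is.null(time)) length(field$times)
        else which.min(abs(field$times - time))
  field$conc[it, , species]
}

#' Per-location temporal period means and their uniformity
#'
#' For a spatio-temporal periodic stimulus, computes the period mean of the
#' output at every grid point (last full cycle, after the drift criterion)
#' and a uniformity statistic \code{(max - min)/mean} over the domain.
#'
#' @param field An \code{stf_field} under a time-periodic stimulus.
#' @param period Stimulus period (default from the stimulus).
#' @param species Species (default: model output).
#' @param drift_tol Convergence tolerance on the local means.
#' @return List with \code{local_means}, \code{positions}, \code{uniformity},
#'   \code{level} (spatial average of local means), \code{converged}.
#' @export
local_temporal_mean_profile <- function(field, period = NULL, species = NULL,
                                        drift_tol = 1e-6) {
  stopifnot(inherits(field, "stf_field"))
  mr <- temporal_period_mean(field, period = period, species = species,
                             drift_tol = drift_tol)
  lm_ <- mr$local_means
  list(local_means = lm_, positions = field$positions,
       uniformity = (max(lm_) - min(lm_)) / mean(lm_),
       level = mean(lm_), converged = mr$converged)
}
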