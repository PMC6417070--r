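# ---------------------------------------------------------------------------
# Circuit registry
#
# Each entry defines a reaction network as an evaluable right-hand side.
# Rates are mass-action; where an external signal S acts on a reaction it
# multiplies that reaction's rate (and only that one).  The rhs factories
# are written with vectorized arithmetic so that the same closure serves
# both the well-mixed ODE case (scalar species) and the method-of-lines
# spatial case (one value per grid point).
# ---------------------------------------------------------------------------

.registry <- new.env(parent = emptyenv())

.site_mult <- function(site, active) if (identical(site, active)) quote(S) else 1

# helper used inside rhs factories: multiplier for a candidate signal site
.sm <- function(site, active_site) if (identical(site, active_site)) NULL else 1

.register <- function(model_id, species, params, sites, output,
                      rhs_factory, conserved = FALSE, s_basal = 0.1,
                      initial_state = NULL, description = "") {
  assign(model_id, list(
    model_id = model_id, species = species, params = params, sites = sites,
    output = output, rhs_factory = rhs_factory, conserved = conserved,
    s_basal = s_basal, initial_state = initial_state,
    description = description
  ), envir = .registry)
  invisible(NULL)
}

# -- two-node inflow-outflow motif (reversible and irreversible) ------------
.rhs_m1 <- function(p, site) {
  sAB <- site == "A_to_B"; sBA <- site == "B_to_A"; sO <- site == "B_outflow"
  function(x, S) {
    vAB <- p[["k1"]] * (if (sAB) S else 1) * x$A
    vBA <- p[["k11"]] * (if (sBA) S else 1) * x$B
    vO  <- p[["k2"]] * (if (sO) S else 1) * x$B
    list(A = p[["k0"]] - vAB + vBA,
         B = vAB - vBA - vO)
  }
}

# -- three-node motifs -------------------------------------------------------
.rhs_m32 <- function(p, site) {
  sAB <- site == "A_to_B"; sBA <- site == "B_to_A"
  sBC <- site == "B_to_C"; sCA <- site == "C_to_A"
  function(x, S) {
    vAB <- p[["k1"]]  * (if (sAB) S else 1) * x$A
    vBA <- p[["k11"]] * (if (sBA) S else 1) * x$B
    vBC <- p[["k32"]] * (if (sBC) S else 1) * x$B
    vCA <- p[["k31"]] * (if (sCA) S else 1) * x$C
    list(A = p[["k0"]] - vAB + vBA + vCA,
         B = vAB - vBA - p[["k2"]] * x$B - vBC,
         C = vBC - p[["k33"]] * x$C - vCA)
  }
}

.rhs_m34 <- function(p, site) {
  sAB <- site == "A_to_B"; sBA <- site == "B_to_A"
  sBC <- site == "B_to_C"; sCA <- site == "C_to_A"; sO <- site == "B_outflow"
  function(x, S) {
    vAB <- p[["k1"]]  * (if (sAB) S else 1) * x$A
    vBA <- p[["k11"]] * (if (sBA) S else 1) * x$B
    vBC <- p[["k32"]] * (if (sBC) S else 1) * x$B
    vCA <- p[["k31"]] * (if (sCA) S else 1) * x$C
    vO  <- p[["k2"]]  * (if (sO) S else 1) * x$B
    list(A = p[["k0"]] - vAB + vBA + vCA,
         B = vAB - vBA - vO - vBC,
         C = vBC + p[["k3"]] - vCA)
  }
}

.rhs_rev3 <- function(p, site) {
  sAB <- site == "A_to_B"; sBA <- site == "B_to_A"
  sBC <- site == "B_to_C"; sCA <- site == "C_to_A"
  sAC <- site == "A_to_C"; sCB <- site == "C_to_B"
  function(x, S) {
    vAB <- p[["k1"]]  * (if (sAB) S else 1) * x$A
    vBA <- p[["k11"]] * (if (sBA) S else 1) * x$B
    vBC <- p[["k32"]] * (if (sBC) S else 1) * x$B
    vCA <- p[["k31"]] * (if (sCA) S else 1) * x$C
    vAC <- p[["k13"]] * (if (sAC) S else 1) * x$A
    vCB <- p[["k23"]] * (if (sCB) S else 1) * x$C
    list(A = p[["k0"]] - vAB + vBA + vCA - vAC,
         B = vAB - vBA - p[["k2"]] * x$B - vBC + vCB,
         C = vBC - p[["k33"]] * x$C - vCA + vAC - vCB)
  }
}

# -- transcritical (autocatalytic, closed) circuit ---------------------------
.rhs_tc <- function(p, site) {
  sAB <- site == "A_to_B"; sBA <- site == "B_to_A"
  function(x, S) {
    vAB  <- p[["k1"]] * (if (sAB) S else 1) * x$A
    vBA  <- p[["k2"]] * (if (sBA) S else 1) * x$B
    vcat <- p[["k3_tc"]] * x$B * x$C
    vrel <- p[["k4"]] * x$C
    list(A = -vAB + vBA,
         B = vAB - vBA - vcat + vrel,
         C = vcat - vrel)
  }
}

# -- incoherent feedforward (covalent-modification readout) ------------------
.rhs_kr09 <- function(p, site) {
  function(x, S) {
    list(A = p[["ka"]] * S - p[["k_minus_a"]] * x$A,
         I = p[["ki"]] * S - p[["k_minus_i"]] * x$I,
         Rstar = p[["kf"]] * x$A * (p[["RT"]] - x$Rstar) -
           p[["kr"]] * x$I * x$Rstar)
  }
}

# -- hybrid circuits: signal regulates inflow and outflow via A and I legs ---
.rhs_hyb_xai <- function(p, site) {
  function(x, S) {
    list(X = p[["k0_h"]] * x$A - p[["k2_h"]] * x$I * x$X,
         A = p[["ka"]] * S - p[["k_minus_a"]] * x$A,
         I = p[["ki"]] * S - p[["k_minus_i"]] * x$I)
  }
}

.rhs_hyb_s2 <- function(p, site) {
  function(x, S) {
    vS2 <- p[["k11_h"]] * S^2 * x$X2
    list(X1 = p[["k0_h"]] * x$A - p[["k1_h"]] * x$X1 + vS2,
         X2 = p[["k1_h"]] * x$X1 - vS2 - p[["k2_h"]] * x$I * x$X2,
         A = p[["ka"]] * S - p[["k_minus_a"]] * x$A,
         I = p[["ki"]] * S - p[["k_minus_i"]] * x$I)
  }
}

.rhs_hyb_auto <- function(p, site) {
  function(x, S) {
    vauto <- p[["k11_h"]] * x$X1 * x$X2
    list(X1 = p[["k0_h"]] * x$A - p[["k1_h"]] * x$X1 + vauto,
         X2 = p[["k1_h"]] * x$X1 - vauto - p[["k2_h"]] * x$I * x$X2,
         A = p[["ka"]] * S - p[["k_minus_a"]] * x$A,
         I = p[["ki"]] * S - p[["k_minus_i"]] * x$I)
  }
}

# signal-transduction legs shared by the feedforward-regulated hybrids:
# fast excitation, slow inhibition (the canonical asymmetric regime), with
# the regulated output reaction fast enough to track the A/I ratio
.leg_params <- c(ka = 1, k_minus_a = 1, ki = 1, k_minus_i = 0.2)

.register("DR08_M1_IRREV", c("A", "B"),
          c(k0 = 1, k1 = 1, k11 = 0, k2 = 1),
          c("A_to_B", "B_outflow"), "B", .rhs_m1,
          description = "two-node inflow-outflow motif, irreversible A->B")
.register("DR08_M1_REV", c("A", "B"),
          c(k0 = 1, k1 = 1, k11 = 1, k2 = 1),
          c("A_to_B", "B_to_A", "B_outflow"), "B", .rhs_m1,
          description = "two-node inflow-outflow motif, reversible A<->B")
.register("DR08_M32", c("A", "B", "C"),
          c(k0 = 1, k1 = 1, k11 = 1, k2 = 1, k32 = 1, k31 = 1, k33 = 1),
          c("A_to_B", "B_to_A", "B_to_C", "C_to_A"), "B", .rhs_m32,
          description = "three-node cyclic motif, outflow at B and C")
.register("DR08_M34", c("A", "B", "C"),
          c(k0 = 1, k1 = 1, k11 = 1, k2 = 1, k32 = 1, k31 = 1, k3 = 1),
          c("A_to_B", "B_to_A", "B_to_C", "C_to_A", "B_outflow"), "B", .rhs_m34,
          description = "three-node cyclic motif, single outflow at B, inflow at A and C")
.register("REV3", c("A", "B", "C"),
          c(k0 = 1, k1 = 1, k11 = 1, k2 = 1, k32 = 1, k31 = 1, k33 = 1,
            k13 = 1, k23 = 1),
          c("A_to_B", "B_to_A", "B_to_C", "C_to_A", "A_to_C", "C_to_B"),
          "B", .rhs_rev3,
          description = "fully reversible three-node motif, outflow at B and C")
.register("TC", c("A", "B", "C"),
          c(k1 = 1, k2 = 1, k3_tc = 1, k4 = 1, Xt = 5),
          c("A_to_B", "B_to_A"), "B", .rhs_tc, conserved = TRUE, s_basal = 0.5,
          initial_state = function(p, S) {
            B <- p[["k4"]] / p[["k3_tc"]]
            A <- p[["k2"]] * p[["k4"]] / (p[["k3_tc"]] * p[["k1"]] * S)
            c(A = A, B = B, C = p[["Xt"]] - A - B)
          },
          description = "closed transcritical circuit with autocatalytic B->C")
.register("KR09", c("A", "I", "Rstar"),
          # canonical regime: fast excitation, slow inhibition, and a readout
          # cycle fast enough to track the A/I ratio quasi-steadily
          c(ka = 1, k_minus_a = 1, ki = 1, k_minus_i = 0.2, kf = 10, kr = 10,
            RT = 1),
          "S_input", "Rstar", .rhs_kr09,
          description = "incoherent feedforward loop driving a covalent cycle")
.register("HYB_XAI", c("X", "A", "I"),
          c(k0_h = 1, k2_h = 10, .leg_params),
          "dual_inflow_outflow", "X", .rhs_hyb_xai,
          description = "hybrid: signal regulates inflow (via A) and outflow (via I) of X")
.register("HYB_S2", c("X1", "X2", "A", "I"),
          # the quadratic signal regulation is the dominant ("stronger") pathway
          c(k0_h = 1, k1_h = 1, k11_h = 10, k2_h = 10, .leg_params),
          "dual_inflow_outflow", "X2", .rhs_hyb_s2,
          description = "hybrid with quadratic signal regulation of the X2->X1 reaction")
.register("HYB_AUTO", c("X1", "X2", "A", "I"),
          # k11_h < k1_h / X2_basal keeps the autocatalytic branch subcritical
          c(k0_h = 1, k1_h = 1, k11_h = 10, k2_h = 10, .leg_params),
          "dual_inflow_outflow", "X2", .rhs_hyb_auto,
          description = "hybrid with autocatalytic X2->X1 conversion (mediated by X1)")

#' Registered circuit identifiers
#'
#' @return Character vector of model ids available to [build_circuit()].
#' @export
circuit_ids <- function() sort(ls(.registry))

.get_entry <- function(model_id) {
  if (!is.character(model_id) || length(model_id) != 1L ||
      !exists(model_id, envir = .registry, inherits = FALSE)) {
    stop("unknown model_id: ", paste(model_id, collapse = ", "),
         " (see circuit_ids())", call. = FALSE)
  }
  get(model_id, envir = .registry, inherits = FALSE)
}

#' Admissible signal sites for a circuit topology
#'
#' The external signal acts multiplicatively on the rate of exactly one
#' reaction; which reactions are available depends on the network topology.
#' The feedforward and hybrid circuits expose a single composite site, since
#' there the signal drives both the activating and inhibiting legs.
#'
#' @param model_id One of [circuit_ids()].
#' @return Character vector of valid signal sites.
#' @export
list_signal_sites <- function(model_id) .get_entry(model_id)$sites

#' Build a fully parameterized circuit model
#'
#' Looks up a circuit in the closed registry, applies parameter overrides and
#' diffusivity annotations, and validates the result. For the transcritical
#' circuit the physical feasibility bound
#' \code{Xt > (k4/k3_tc) * (1 + k2/(k1*S))} is checked at the basal signal:
#' below it the nonzero-C steady-state branch (the basis for adaptation)
#' does not exist.
#'
#' @param model_id One of [circuit_ids()].
#' @param signal_site A site from [list_signal_sites()] for this topology.
#' @param overrides Named list/vector of nonnegative parameter overrides;
#'   unknown names are rejected.
#' @param diffusivities Named nonnegative vector of per-species diffusivities
#'   (length^2 / time); species not named keep diffusivity 0.
#' @param s_basal Basal signal level the model is prepared for (used for the
#'   transcritical feasibility check and as the default pre-equilibration
#'   signal). Defaults to the registry's per-model basal.
#' @return An object of class \code{circuit_model}.
#' @export
build_circuit <- function(model_id, signal_site = NULL, overrides = list(),
                          diffusivities = NULL, s_basal = NULL) {
  entry <- .get_entry(model_id)
  if (is.null(signal_site)) signal_site <- entry$sites[[1L]]
  if (!is.character(signal_site) || length(signal_site) != 1L ||
      !(signal_site %in% entry$sites)) {
    stop("invalid signal site '", paste(signal_site, collapse = ","),
         "' for ", model_id, "; valid sites: ",
         paste(entry$sites, collapse = ", "), call. = FALSE)
  }
  params <- entry$params
  if (length(overrides)) {
    ov <- unlist(overrides)
    bad <- setdiff(names(ov), names(params))
    if (length(bad)) {
      stop("unknown parameter(s) for ", model_id, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(ov)) || any(ov < 0)) {
      stop("parameter overrides must be finite and nonnegative", call. = FALSE)
    }
    params[names(ov)] <- ov
  }
  kd <- stats::setNames(numeric(length(entry$species)), entry$species)
  if (!is.null(diffusivities)) {
    dv <- unlist(diffusivities)
    bad <- setdiff(names(dv), entry$species)
    if (length(bad)) {
      stop("diffusivities name unknown species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(dv)) || any(dv < 0)) {
      stop("diffusivities must be finite and nonnegative", call. = FALSE)
    }
    kd[names(dv)] <- dv
  }
  if (is.null(s_basal)) s_basal <- entry$s_basal
  if (!is.numeric(s_basal) || length(s_basal) != 1L || s_basal < 0) {
    stop("s_basal must be a single nonnegative number", call. = FALSE)
  }
  if (identical(model_id, "TC")) {
    bound <- (params[["k4"]] / params[["k3_tc"]]) *
      (1 + params[["k2"]] / (params[["k1"]] * s_basal))
    if (!is.finite(bound) || params[["Xt"]] <= bound) {
      stop(sprintf(paste0(
        "TC circuit infeasible at basal signal S = %g: requires Xt > ",
        "(k4/k3_tc)(1 + k2/(k1*S)) = %g but Xt = %g"),
        s_basal, bound, params[["Xt"]]), call. = FALSE)
    }
  }
  model <- structure(list(
    model_id = model_id,
    species = entry$species,
    params = params,
    signal_site = signal_site,
    output = entry$output,
    conserved = entry$conserved,
    diffusivities = kd,
    s_basal = s_basal,
    description = entry$description,
    rhs = entry$rhs_factory(as.list(params), signal_site),
    initial_state = entry$initial_state
  ), class = "circuit_model")
  model
}

#' @export
print.circuit_model <- function(x, ...) {
  cat("<circuit_model> ", x$model_id, ": ", x$description, "\n", sep = "")
  cat("  species:     ", paste(x$species, collapse = ", "),
      "  (output: ", x$output, ")\n", sep = "")
  cat("  signal site: ", x$signal_site, "\n", sep = "")
  cat("  params:      ",
      paste(names(x$params), signif(x$params, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  if (any(x$diffusivities > 0)) {
    d <- x$diffusivities[x$diffusivities > 0]
    cat("  diffusible:  ",
        paste(names(d), signif(d, 4), sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  if (x$conserved) cat("  conserved total: A+B+C = ", x$params[["Xt"]], "\n",
                       sep = "")
  invisible(x)
}

#' Evaluate a circuit's right-hand side
#'
#' Exact algebraic evaluation of the model equations at a given state and
#' signal, with the signal inserted multiplicatively at the configured site
#' only. State components may be vectors of common length (one value per
#' spatial grid point); the reaction terms are purely local.
#'
#' @param model A \code{circuit_model}.
#' @param state Named (or ordered) nonnegative concentration vector, or a
#'   matrix with one column per species.
#' @param signal Nonnegative signal value (scalar, or vector matching the
#'   grid dimension of \code{state}).
#' @param time Time at which the evaluation is made (unused by the autonomous
#'   rate laws; kept for interface completeness).
#' @return Named derivative vector (or matrix) matching \code{state}.
#' @export
evaluate_rhs <- function(model, state, signal, time = 0) {
  stopifnot(inherits(model, "circuit_model"))
  nsp <- length(model$species)
  if (is.matrix(state)) {
    if (ncol(state) != nsp) stop("state must have one column per species")
    x <- stats::setNames(lapply(seq_len(nsp), function(j) state[, j]),
                         model$species)
  } else {
    if (length(state) != nsp) {
      stop("state length ", length(state), " does not match species count ",
           nsp, call. = FALSE)
    }
    if (!is.null(names(state))) {
      if (!setequal(names(state), model$species)) {
        stop("state names must match species: ",
             paste(model$species, collapse = ", "), call. = FALSE)
      }
      state <- state[model$species]
    }
    x <- stats::setNames(as.list(as.numeric(state)), model$species)
  }
  if (any(unlist(x) < 0) || any(signal < 0)) {
    stop("state and signal must be nonnegative", call. = FALSE)
  }
  d <- model$rhs(x, signal)
  if (is.matrix(state)) {
    out <- do.call(cbind, d[model$species])
    colnames(out) <- model$species
    out
  } else {
    stats::setNames(as.numeric(unlist(d[model$species])), model$species)
  }
}

#' Conserved total of a closed circuit
#'
#' The transcritical circuit is closed: A + B + C is invariant under the
#' dynamics for any state and signal. Open (inflow-outflow, feedforward,
#' hybrid) circuits have no conserved total and return \code{NULL}.
#'
#' @param model A \code{circuit_model}.
#' @param state Concentration vector (named or in species order).
#' @return The scalar total, or \code{NULL} for open systems.
#' @export
conserved_total <- function(model, state) {
  stopifnot(inherits(model, "circuit_model"))
  if (!model$conserved) return(NULL)
  if (!is.null(names(state))) state <- state[model$species]
  sum(as.numeric(state))
}

# Analytic basal steady state used to seed pre-equilibration.  Falls back to
# a unit start when no closed form is registered.
.initial_guess <- function(model, S) {
  if (!is.null(model$initial_state)) {
    return(model$initial_state(as.list(model$params), S))
  }
  stats::setNames(rep(1, length(model$species)), model$species)
}
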