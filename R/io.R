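# ---------------------------------------------------------------------------
# Structured-text (YAML) configuration for circuits and stimuli, and
# CSV/JSON export of trajectories and fields.
# ---------------------------------------------------------------------------

#' Write a circuit + stimulus configuration
#'
#' Serializes a circuit model (id, parameters, signal site, diffusivities,
#' basal signal) and optionally a stimulus spec to a YAML file that
#' [read_config()] can rebuild exactly.
#'
#' @param path Output file path.
#' @param model A \code{circuit_model}.
#' @param stim Optional \code{stimulus}.
#' @return Invisibly, \code{path}.
#' @export
write_config <- function(path, model, stim = NULL) {
  stopifnot(inherits(model, "circuit_model"))
  cfg <- list(circuit = list(
    model_id = model$model_id,
    signal_site = model$signal_site,
    params = as.list(model$params),
    diffusivities = as.list(model$diffusivities),
    s_basal = model$s_basal
  ))
  if (!is.null(stim)) {
    stopifnot(inherits(stim, "stimulus"))
    cfg$stimulus <- unclass(stim)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a circuit + stimulus configuration
#'
#' @param path YAML file written by [write_config()] (or hand-authored with
#'   the same fields).
#' @return List with \code{model} (a rebuilt \code{circuit_model}) and
#'   \code{stim} (a \code{stimulus} or \code{NULL}).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$circuit$model_id)) {
    stop("config lacks circuit$model_id", call. = FALSE)
  }
  cc <- cfg$circuit
  kd <- cc$diffusivities
  if (!is.null(kd)) kd <- kd[vapply(kd, function(v) v > 0, logical(1))]
  model <- build_circuit(cc$model_id, cc$signal_site,
                         overrides = cc$params %||% list(),
                         diffusivities = if (length(kd)) kd else NULL,
                         s_basal = cc$s_basal)
  stim <- NULL
  if (!is.null(cfg$stimulus)) {
    stim <- do.call(stimulus, cfg$stimulus)
  }
  list(model = model, stim = stim)
}

#' Export a trajectory or field as long-format CSV
#'
#' Columns: \code{time}, (\code{position},) \code{species}, \code{value}.
#' A JSON metadata sidecar (\code{<path>.json}) records the model, stimulus
#' and solver settings.
#'
#' @param x A \code{trajectory} or \code{stf_field}.
#' @param path CSV output path.
#' @param sidecar Write the JSON metadata sidecar.
#' @return Invisibly, \code{path}.
#' @export
export_trajectory <- function(x, path, sidecar = TRUE) {
  if (inherits(x, "trajectory")) {
    df <- data.frame(
      time = rep(x$times, times = ncol(x$conc)),
      species = rep(colnames(x$conc), each = length(x$times)),
      value = as.vector(x$conc)
    )
  } else if (inherits(x, "stf_field")) {
    d <- dim(x$conc)
    df <- data.frame(
      time = rep(x$times, times = d[2] * d[3]),
      position = rep(rep(x$positions, each = d[1]), times = d[3]),
      species = rep(dimnames(x$conc)[[3]], each = d[1] * d[2]),
      value = as.vector(x$conc)
    )
  } else stop("x must be a trajectory or stf_field", call. = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    meta <- list(model_id = x$model$model_id,
                 signal_site = x$model$signal_site,
                 params = as.list(x$model$params),
                 diffusivities = as.list(x$model$diffusivities),
                 stimulus = unclass(x$stim),
                 status = x$status,
                 settings = x$settings)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
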