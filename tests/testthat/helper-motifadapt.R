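# Shared helpers: cheap builders and a session cache for expensive runs
# (several acceptance checks share the same simulations).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache, inherits = FALSE)
}

# random nonnegative state for a model, log-uniform over several decades
random_state <- function(model, scale = 10) {
  n <- length(model$species)
  stats::setNames(exp(stats::runif(n, log(1e-3), log(scale))), model$species)
}

# all registered models built with their default site
all_default_models <- function() {
  lapply(circuit_ids(), function(id) build_circuit(id))
}
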