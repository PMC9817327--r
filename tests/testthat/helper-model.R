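# Shared fixtures, built once per test run.
.tx_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.tx_cache[[name]])) assign(name, force(expr), envir = .tx_cache)
  .tx_cache[[name]]
}

base_params <- function() cached("params", load_parameters())
base_model <- function() cached("model", build_model(base_params()))
base_cea <- function() cached("cea", run_base_case(base_model()))

# A random valid parameter assignment: every sampled parameter drawn
# uniformly within its printed limits (probabilities/utilities stay in
# [0, 1], costs non-negative, relative risks positive by construction).
random_values <- function(model, seed) {
  set.seed(seed)
  vals <- model_values(model$tree)
  for (p in model$params) {
    if (p$sample && p$high > p$low)
      vals[[p$name]] <- runif(1, p$low, p$high)
  }
  vals
}
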