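# shared helpers: tiny models and observation plumbing

onehot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

# a 2-state, 1-modality model with a soft likelihood and a non-flat prior,
# small enough for exact enumeration
soft_two_state <- function(D = c(0.3, 0.7), counts = matrix(c(4, 1, 1, 4), 2)) {
  gen_model(
    factors = list(factor_spec("state", 2)),
    modalities = list(modality_spec("signal", 2, 1L)),
    A = list(counts),
    B = list(array(diag(2), c(2, 2, 1))),
    D = list(D))
}

# full named observation list for a sentinel agent at one epoch
sentinel_obs <- function(model, world, agent_index, heard = NULL) {
  env <- observe_environment(world, agent_index, model)
  o <- stats::setNames(vector("list", length(model$modalities)),
                       vapply(model$modalities, `[[`, "", "name"))
  for (k in names(env)) o[[k]] <- env[[k]]
  if (!is.null(heard)) for (k in names(heard)) o[[k]] <- heard[[k]]
  o
}

first_true <- function(flags) {
  i <- which(flags)
  if (length(i)) i[1] else NA_integer_
}
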