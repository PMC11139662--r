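# Expected-free-energy-gated Dirichlet learning with Bayes-optimal
# forgetting. Each observation contributes a unit coincidence Delta_a; the
# update is committed with probability sigma(-alpha * G) over the two
# policies {keep, update}, and the total counts decay multiplicatively so
# that they saturate at eta.

#' Coincidence increment for one observation
#'
#' The outer product of the observation vector with the parent state
#' posteriors at that time; its entries sum to one, so each observation can
#' contribute at most one Dirichlet count.
#'
#' @param obs observation vector over outcome levels (one-hot or soft).
#' @param state_dists list of parent state posteriors in parent-axis order.
#' @return count-increment array shaped like the modality's likelihood.
#' @export
coincidence <- function(obs, state_dists) {
  outer_product(c(list(obs), state_dists))
}

#' Probability of committing a Dirichlet update
#'
#' Evaluates the expected free energy of the parameters with and without the
#' increment and returns `P(update) = softmax(-alpha * c(G(a), G(a + delta)))[2]`.
#'
#' @param a current count array.
#' @param delta increment array (same shape).
#' @param c_counts preference counts over outcomes (default flat).
#' @param alpha expected-free-energy precision; large `alpha` turns the
#'   Bayesian model average into model selection.
#' @return scalar probability in `[0, 1]`.
#' @export
update_gate <- function(a, delta, c_counts = NULL, alpha = 8) {
  g0 <- efe_parameters(a, c_counts)$total
  g1 <- efe_parameters(a + delta, c_counts)$total
  .softmax(-alpha * c(g0, g1))[2]
}

#' Apply a gated, forgetting Dirichlet update
#'
#' `a <- (a + p * delta) * eta / (eta + p)`: the gated increment followed by
#' a multiplicative decay whose fixed point keeps the total counts at `eta`.
#'
#' @param a count array.
#' @param delta increment array.
#' @param p_update commitment probability in `[0, 1]`.
#' @param eta forgetting hyperprior (count saturation level).
#' @return updated count array.
#' @export
apply_update <- function(a, delta, p_update, eta) {
  stopifnot(p_update >= 0, p_update <= 1, eta > 0)
  (a + p_update * delta) * (eta / (eta + p_update))
}

# Run the learning pass for one agent at the end of an episode, using the
# smoothed state posteriors. Returns the model (with refreshed caches) and
# diagnostics: per-update P(update), KL between tensors before/after (the
# "free energy of learning"), and the learnable set.
#
# batch = FALSE gates and decays each epoch's unit coincidence in temporal
# order; batch = TRUE accumulates the episode's coincidences first
# (Einstein summation over time) and takes one gated, decayed update whose
# forgetting uses the committed mass p * sum(Delta a), preserving the eta
# fixed point.
.learn_episode <- function(model, beliefs, observations, batch = TRUE,
                           priors = NULL) {
  learnable <- which(vapply(model$modalities, function(g) isTRUE(g$learnable),
                            logical(1)))
  if (!length(learnable)) {
    return(list(model = model, info = NULL))
  }
  t_end <- length(observations)
  before <- model$A[learnable]
  p_log <- list()
  decay <- stats::setNames(rep(1, length(learnable)),
                           as.character(learnable))
  for (g in learnable) {
    spec <- model$modalities[[g]]
    a <- model$A[[g]]
    am <- .as_mat(a)
    # with a consolidated (reduction) prior, forgetting applies to the
    # accumulated data counts only: posterior = prior + data throughout
    pm <- NULL
    if (!is.null(priors) && !is.null(priors[[as.character(g)]])) {
      pm <- .as_mat(priors[[as.character(g)]])
    }
    if (batch) {
      dm <- matrix(0, nrow(am), ncol(am))
      n_obs <- 0
      for (tau in seq_len(t_end)) {
        o <- observations[[tau]][[g]]
        if (is.null(o)) next
        w <- o
        for (pf in spec$parents) {
          w <- as.vector(outer(w, beliefs$s[[pf]][, tau]))
        }
        dm <- dm + matrix(w, nrow = nrow(am))
        n_obs <- n_obs + 1
      }
      if (n_obs > 0) {
        p <- .softmax(-model$alpha * c(.neg_mi(am), .neg_mi(am + dm)))[2]
        f <- model$eta / (model$eta + p * sum(dm))
        if (is.null(pm)) {
          am <- (am + p * dm) * f
        } else {
          dat <- pmax(am - pm, 0)
          am <- pm + (dat + p * dm) * f
        }
        decay[[as.character(g)]] <- f
        p_log[[spec$name]] <- p
      }
    } else {
      g_cur <- .neg_mi(am)
      ps <- numeric(t_end)
      for (tau in seq_len(t_end)) {
        o <- observations[[tau]][[g]]
        if (is.null(o)) { ps[tau] <- NA_real_; next }
        w <- o
        for (pf in spec$parents) {
          w <- as.vector(outer(w, beliefs$s[[pf]][, tau]))
        }
        dm <- matrix(w, nrow = nrow(am))
        g_new <- .neg_mi(am + dm)
        p <- .softmax(-model$alpha * c(g_cur, g_new))[2]
        f <- model$eta / (model$eta + p)
        if (is.null(pm)) {
          am <- (am + p * dm) * f
        } else {
          dat <- pmax(am - pm, 0)
          am <- pm + (dat + p * dm) * f
        }
        decay[[as.character(g)]] <- decay[[as.character(g)]] * f
        g_cur <- .neg_mi(am)
        ps[tau] <- p
      }
      p_log[[spec$name]] <- ps
    }
    model$A[[g]] <- array(am, dim = dim(a))
  }
  model <- refresh_model(model)
  dF_learn <- sum(vapply(seq_along(learnable), function(i) {
    dirichlet_kl(model$A[[learnable[i]]], before[[i]])
  }, numeric(1)))
  list(model = model,
       info = list(p_update = p_log, learning_kl = dF_learn,
                   learnable = learnable, decay = decay))
}
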