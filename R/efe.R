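# Expected free energy of actions (risk + ambiguity - novelty) and of
# likelihood parameters (negative mutual information minus expected cost).

# centred expected log-preferences over outcomes: phi(c) minus its mean.
# Log-preferences are defined up to an additive constant, and centring makes
# the cost term vanish identically for flat preferences.
.pref_log <- function(c_counts) {
  phi <- digamma(c_counts) - digamma(sum(c_counts))
  phi - mean(phi)
}

#' Expected free energy of one action
#'
#' Propagates the current state posteriors one step under the action,
#' predicts outcomes through the mean likelihoods, and scores each modality:
#' risk is the KL divergence from predicted outcomes to the (softmax of the)
#' preferences; ambiguity is the expected conditional outcome entropy;
#' novelty is the expected Dirichlet information gain of learnable
#' likelihoods (count-based approximation `0.5 * (1/a - 1/colsum(a))`).
#'
#' @param model a `gen_model`.
#' @param beliefs a `belief_state` with a current state posterior.
#' @param action action index for the controllable factor.
#' @return list with per-modality matrices and totals `risk`, `ambiguity`,
#'   `novelty` and `total = risk + ambiguity - novelty` (nats).
#' @export
efe_policy <- function(model, beliefs, action) {
  nf <- length(model$factors)
  pred <- vector("list", nf)
  for (f in seq_len(nf)) {
    if (isTRUE(model$factors[[f]]$controllable)) {
      v <- numeric(model$factors[[f]]$n_states)
      v[action] <- 1
      pred[[f]] <- v
    } else {
      pred[[f]] <- predictive_posterior(beliefs, model, f)
    }
  }
  risk <- ambiguity <- novelty <- 0
  per <- matrix(0, nrow = length(model$modalities), ncol = 3,
                dimnames = list(vapply(model$modalities, `[[`, "", "name"),
                                c("risk", "ambiguity", "novelty")))
  for (g in seq_along(model$modalities)) {
    spec <- model$modalities[[g]]
    w <- 1
    for (pf in spec$parents) w <- as.vector(outer(w, pred[[pf]]))
    o_pred <- as.vector(model$cache[[g]]$mean_mat %*% w)
    pref <- .softmax(.pref_log(model$c_pref[[g]]))
    r <- sum(o_pred * (ln_eps(o_pred) - ln_eps(pref)))
    amb <- sum(model$cache[[g]]$H_cond * w)
    nov <- if (isTRUE(spec$learnable)) sum(model$cache[[g]]$novelty_w * w) else 0
    per[g, ] <- c(r, amb, nov)
    risk <- risk + r; ambiguity <- ambiguity + amb; novelty <- novelty + nov
  }
  list(risk = risk, ambiguity = ambiguity, novelty = novelty,
       total = risk + ambiguity - novelty, per_modality = per)
}

#' Expected free energy over all actions
#'
#' @inheritParams efe_policy
#' @return numeric vector of `total` expected free energies per action.
#' @export
efe_all_actions <- function(model, beliefs) {
  ctrl <- which(vapply(model$factors, function(f) isTRUE(f$controllable),
                       logical(1)))
  n_act <- model$factors[[ctrl[1]]]$n_paths
  vapply(seq_len(n_act), function(u) efe_policy(model, beliefs, u)$total,
         numeric(1))
}

#' Expected free energy of a likelihood's Dirichlet parameters
#'
#' Normalises the counts over all elements to the joint distribution over
#' outcomes and parent-state combinations; the mutual information of that
#' joint is the epistemic value of the parameters, and the expected cost is
#' the preference-weighted outcome marginal (identically zero for flat
#' preferences). `total = -mutual_information - expected_cost`; lower (more
#' negative) totals mark more informative mappings.
#'
#' @param a strictly positive Dirichlet count array (outcome axis first).
#' @param c_counts preference counts over outcome levels (default flat).
#' @return list with `mutual_information`, `expected_cost`, `total`.
#' @export
efe_parameters <- function(a, c_counts = NULL) {
  mi <- joint_mutual_information(a)
  cost <- 0
  if (!is.null(c_counts)) {
    m <- .as_mat(a)
    p_out <- rowSums(m) / sum(m)
    cost <- sum(.pref_log(c_counts) * p_out)
  }
  list(mutual_information = mi, expected_cost = cost, total = -mi - cost)
}

# fast internal: -MI of a count matrix (flat preferences)
.neg_mi <- function(m) {
  p <- m / sum(m)
  -(.entropy(rowSums(p)) + .entropy(colSums(p)) - .entropy(as.vector(p)))
}
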