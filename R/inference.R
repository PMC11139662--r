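# Variational message passing for state and path posteriors, action
# selection and variational free-energy accounting.
#
# Posterior expectations over hidden states are fixed-point iterated:
# s_tau^f = softmax(likelihood messages + forward message + backward
# message), sweeping over all time steps of the episode so far until the
# free-energy change falls below `tol` (1/128 nats) or the sweep budget is
# exhausted. Likelihood messages default to the Jensen bound
# ln(o . mu(a) . s_others), which exploits sparse likelihood tensors; the
# digamma form o . phi(a) . s_others is available as `mode = "digamma"`.

#' Create an empty belief state for a model
#'
#' @param model a `gen_model`.
#' @return object of class `belief_state` holding per-factor state posteriors
#'   (one column per time step), path posteriors, the policy posterior over
#'   gaze actions, the realised action history and free-energy diagnostics.
#' @export
new_beliefs <- function(model) {
  structure(list(
    s = lapply(model$factors, function(f) {
      matrix(numeric(0), nrow = f$n_states, ncol = 0)
    }),
    paths = lapply(model$factors, function(f) rep(1 / f$n_paths, f$n_paths)),
    policy = NULL,
    actions = integer(0),
    F_trace = numeric(0),
    F_last = NA_real_,
    acc = NULL,
    sweeps = integer(0),
    converged = logical(0)),
    class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  t <- ncol(x$s[[1]])
  cat("<belief_state>", t, "time step(s); F =",
      format(x$F_last, digits = 4), "\n")
  invisible(x)
}

# log-likelihood message from modality g to factor f at weight vector w
# (w = vec(outer(o, s_otherparents)) in axis order)
.lik_message <- function(model, g, f, w, mode) {
  spec <- model$modalities[[g]]
  slot <- match(f, spec$parents)
  if (mode == "bound") {
    ln_eps(crossprod(model$cache[[g]]$pp_mean[[slot]], w))
  } else {
    crossprod(model$cache[[g]]$pp_phi[[slot]], w)
  }
}

#' Log-likelihood message from one modality to one parent factor
#'
#' Contracts the modality's likelihood statistics over the observation and
#' the posteriors of all other parent factors, returning the log-domain
#' message for `target_factor`. `mode = "bound"` uses the Jensen bound on the
#' expected log-likelihood (the column-normalised mean); `mode = "digamma"`
#' uses the exact Dirichlet expectation `phi(a)`.
#'
#' @param a ignored if `model` supplied; kept for direct use: a count array.
#' @param obs observation vector (one-hot or soft) over outcome levels.
#' @param state_dists list of posterior vectors for every parent factor, in
#'   the order of the likelihood's parent axes.
#' @param target_axis which parent axis (1-based among parents) to message.
#' @param mode `"bound"` or `"digamma"`.
#' @return log-domain message vector over the target factor's states.
#' @export
likelihood_message <- function(a, obs, state_dists, target_axis,
                               mode = c("bound", "digamma")) {
  mode <- match.arg(mode)
  d <- dim(a); if (is.null(d)) d <- length(a)
  k <- length(d)
  ax <- target_axis + 1L
  if (ax < 2 || ax > k) stop("target_axis is not a parent axis", call. = FALSE)
  tens <- if (mode == "bound") dirichlet_mean(a) else expected_log(a)
  perm <- c(setdiff(seq_len(k), ax), ax)
  M <- matrix(aperm(tens, perm), ncol = d[ax])
  others <- state_dists[-target_axis]
  w <- Reduce(function(x, y) as.vector(outer(x, y)), c(list(obs), others))
  v <- as.vector(crossprod(M, w))
  if (mode == "bound") ln_eps(v) else v
}

# volatility hedge for belief propagation: deterministic transitions carry
# exact zeros whose floored logarithms (-32) can lock mean-field sweeps
# into dynamically inconsistent minima (a mistaken early commitment can
# then never be revised by later evidence). Beliefs therefore propagate
# through a transition mixed with a small uniform jump; the world process
# itself stays deterministic.
.kappa_mix <- 1 / 32

# path-averaged transition matrix (probability domain) for factor f; for
# the controllable factor the realised action's slice applies to the
# transition into time tau (tau >= 2). Uncontrolled factors are hedged
# with the uniform jump above.
.trans_mat <- function(model, beliefs, f, tau = NULL) {
  B <- model$B[[f]]
  fs <- model$factors[[f]]
  if (isTRUE(fs$controllable) && !is.null(tau)) {
    act <- beliefs$actions[tau - 1L]
    if (is.na(act) || length(act) == 0) act <- 2L
    return(B[, , act])
  }
  u <- beliefs$paths[[f]]
  M <- B[, , 1L] * u[1L]
  if (fs$n_paths > 1L) for (k in 2:fs$n_paths) M <- M + B[, , k] * u[k]
  (1 - .kappa_mix) * M + .kappa_mix / fs$n_states
}

.bbar <- function(model, beliefs, f) .trans_mat(model, beliefs, f)

# forward message: log of the path-averaged predictive density
.fwd_msg <- function(model, beliefs, f, tau) {
  ln_eps(.trans_mat(model, beliefs, f, tau) %*% beliefs$s[[f]][, tau - 1L])
}

# backward message: transpose-propagation of the row-normalised transition
# (the posterior over the earlier state given the later one, under a flat
# prior), log-transformed
.bwd_msg <- function(model, beliefs, f, tau) {
  M <- .trans_mat(model, beliefs, f, tau + 1L)
  rs <- rowSums(M)
  Mn <- M / pmax(rs, .eps)
  ln_eps(crossprod(Mn, pmax(beliefs$s[[f]][, tau + 1L], 0)))
}

#' Infer state (and uncontrolled path) posteriors by fixed-point sweeps
#'
#' @param model a `gen_model`.
#' @param beliefs a `belief_state` (warm start; may hold fewer time steps
#'   than `observations`).
#' @param observations list over time steps; each element a named or
#'   positional list of observation vectors per modality (`NULL` entries are
#'   skipped). One-hot for environmental outcomes, distributions for heard
#'   speech.
#' @param n_sweeps maximum fixed-point sweeps (default 16).
#' @param tol free-energy convergence tolerance in nats (default 1/128).
#' @param mode likelihood message mode, `"bound"` (default) or `"digamma"`.
#' @param window number of trailing time steps re-swept per call (default
#'   8): online updating revisits the recent past; a full smoothing pass
#'   (`window = Inf`) is run before learning. Earlier steps keep their
#'   posteriors and cached accuracy terms.
#' @return updated `belief_state`; non-convergence is recorded in
#'   `$converged`, not an error.
#' @export
infer_states <- function(model, beliefs, observations,
                         n_sweeps = 16, tol = 1 / 128,
                         mode = c("bound", "digamma"), window = 8L) {
  mode <- match.arg(mode)
  t_end <- length(observations)
  t_start <- max(1L, t_end - as.integer(min(window, t_end)) + 1L)
  acc_prev <- beliefs$acc
  nf <- length(model$factors)
  ng <- length(model$modalities)

  # extend state matrices with predictive initialisations
  for (f in seq_len(nf)) {
    while (ncol(beliefs$s[[f]]) < t_end) {
      tcur <- ncol(beliefs$s[[f]])
      init <- if (tcur == 0L) {
        model$D[[f]]
      } else if (isTRUE(model$factors[[f]]$controllable)) {
        act <- beliefs$actions[tcur]
        if (is.na(act)) act <- 2L
        as.vector(model$B[[f]][, , act] %*% beliefs$s[[f]][, tcur])
      } else {
        as.vector(.bbar(model, beliefs, f) %*% beliefs$s[[f]][, tcur])
      }
      beliefs$s[[f]] <- cbind(beliefs$s[[f]], pmax(init, 1e-12) / sum(pmax(init, 1e-12)))
    }
  }

  F_prev <- Inf
  sweeps_done <- 0L
  converged <- FALSE
  for (sweep in seq_len(n_sweeps)) {
    for (tau in t_start:t_end) {
      obs_tau <- observations[[tau]]
      for (f in seq_len(nf)) {
        nsf <- model$factors[[f]]$n_states
        msg <- numeric(nsf)
        for (g in model$children[[f]]) {
          o <- obs_tau[[g]]
          if (is.null(o)) next
          spec <- model$modalities[[g]]
          others <- spec$parents[spec$parents != f]
          w <- o
          for (pf in others) {
            w <- as.vector(outer(w, beliefs$s[[pf]][, tau]))
          }
          msg <- msg + .lik_message(model, g, f, w, mode)
        }
        fwd <- if (tau == 1L) {
          ln_eps(model$D[[f]])
        } else {
          .fwd_msg(model, beliefs, f, tau)
        }
        msg <- msg + as.vector(fwd)
        if (tau < t_end) {
          msg <- msg + as.vector(.bwd_msg(model, beliefs, f, tau))
        }
        beliefs$s[[f]][, tau] <- .softmax(msg)
      }
    }
    # uncontrolled multi-path posteriors from the inferred state sequence
    beliefs <- .update_paths(model, beliefs, t_end)
    Fv <- .free_energy(model, beliefs, observations,
                       acc_prev = acc_prev, from = t_start)
    beliefs$F_trace <- c(beliefs$F_trace, Fv$total)
    sweeps_done <- sweep
    if (is.finite(F_prev) && (F_prev - Fv$total) < tol) {
      converged <- TRUE
      F_prev <- Fv$total
      break
    }
    F_prev <- Fv$total
  }
  Fv <- .free_energy(model, beliefs, observations,
                     acc_prev = acc_prev, from = t_start)
  beliefs$F_last <- Fv$total
  beliefs$acc <- Fv$per_modality_per_time
  beliefs$sweeps <- c(beliefs$sweeps, sweeps_done)
  beliefs$converged <- c(beliefs$converged, converged)
  beliefs
}

# posterior over paths for uncontrolled multi-path factors, given the
# current state posteriors: softmax(ln E + sum_tau s_tau' ln B_u s_{tau-1})
.update_paths <- function(model, beliefs, t_end) {
  for (f in seq_along(model$factors)) {
    fs <- model$factors[[f]]
    if (fs$controllable || fs$n_paths == 1L) next
    logu <- ln_eps(model$E[[f]])
    if (t_end >= 2L) {
      for (u in seq_len(fs$n_paths)) {
        Bu <- model$B[[f]][, , u]
        acc <- 0
        for (tau in 2:t_end) {
          acc <- acc + ln_eps(sum(beliefs$s[[f]][, tau] *
                                    (Bu %*% beliefs$s[[f]][, tau - 1L])))
        }
        logu[u] <- logu[u] + acc
      }
    }
    beliefs$paths[[f]] <- .softmax(logu)
  }
  beliefs
}

#' Infer path posteriors
#'
#' For controllable factors the policy posterior is
#' `softmax(policy_precision * (ln E - G))` with `G` the supplied expected
#' free energy per action; for uncontrolled multi-path factors the posterior
#' follows from the transition likelihood of the inferred state sequence
#' (motion is never observed directly and must be inferred).
#'
#' @param model a `gen_model`.
#' @param beliefs a `belief_state` with at least one inferred time step.
#' @param efe numeric vector of expected free energies, one per action of
#'   the controllable factor (`NULL` leaves the policy at the `E` prior).
#' @return the updated `belief_state` (fields `policy` and `paths`).
#' @export
infer_paths <- function(model, beliefs, efe = NULL) {
  beliefs <- .update_paths(model, beliefs, ncol(beliefs$s[[1]]))
  ctrl <- which(vapply(model$factors, function(f) isTRUE(f$controllable),
                       logical(1)))
  if (length(ctrl)) {
    f <- ctrl[1]
    lnE <- ln_eps(model$E[[f]])
    if (is.null(efe)) efe <- numeric(model$factors[[f]]$n_paths)
    if (any(!is.finite(efe))) stop("efe must be finite", call. = FALSE)
    # snap to a 1e-6 nat grid: actions whose expected free energies differ
    # only by floating-point residue are genuine ties, decided by E and
    # the documented lowest-index rule rather than rounding noise
    efe <- round(efe * 1e6) / 1e6
    beliefs$policy <- .softmax(model$policy_precision * (lnE - efe))
  }
  beliefs
}

#' Select an action from the policy posterior
#'
#' @param pi probability vector over actions.
#' @param mode `"argmax"` (ties break to the lowest index) or `"sample"`.
#' @param seed optional seed for sampling.
#' @return integer action index.
#' @export
select_action <- function(pi, mode = c("argmax", "sample"), seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "argmax") return(which.max(pi))
  if (!is.null(seed)) set.seed(seed)
  sample.int(length(pi), 1L, prob = pi)
}

# internal free energy: complexity of states (and uncontrolled paths)
# against their forward empirical priors, minus per-modality accuracy.
# Accuracy columns for time steps before `from` are reused from
# `acc_prev` (their posteriors are frozen, so they cannot change).
.free_energy <- function(model, beliefs, observations,
                         acc_prev = NULL, from = 1L) {
  t_end <- length(observations)
  ng <- length(model$modalities)
  acc <- matrix(0, nrow = ng, ncol = t_end,
                dimnames = list(vapply(model$modalities, `[[`, "", "name"),
                                NULL))
  if (!is.null(acc_prev) && from > 1L) {
    k <- min(ncol(acc_prev), from - 1L)
    if (k > 0) acc[, seq_len(k)] <- acc_prev[, seq_len(k)]
  }
  complexity <- 0
  for (tau in seq_len(t_end)) {
    for (f in seq_along(model$factors)) {
      s <- beliefs$s[[f]][, tau]
      prior <- if (tau == 1L) {
        ln_eps(model$D[[f]])
      } else {
        as.vector(.fwd_msg(model, beliefs, f, tau))
      }
      complexity <- complexity + sum(s * (ln_eps(s) - prior))
    }
    if (tau < from && !is.null(acc_prev)) next
    obs_tau <- observations[[tau]]
    for (g in seq_len(ng)) {
      o <- obs_tau[[g]]
      if (is.null(o)) next
      spec <- model$modalities[[g]]
      w <- 1
      for (pf in spec$parents) w <- as.vector(outer(w, beliefs$s[[pf]][, tau]))
      pred <- as.vector(model$cache[[g]]$mean_mat %*% w)
      acc[g, tau] <- -sum(o * ln_eps(pred))
    }
  }
  # complexity of uncontrolled path posteriors against E
  for (f in seq_along(model$factors)) {
    fs <- model$factors[[f]]
    if (fs$controllable || fs$n_paths == 1L) next
    u <- beliefs$paths[[f]]
    complexity <- complexity + sum(u * (ln_eps(u) - ln_eps(model$E[[f]])))
  }
  list(total = complexity + sum(acc), complexity = complexity,
       per_modality_per_time = acc)
}

#' Variational free energy of the current beliefs
#'
#' `F = E_Q[ln Q(s) - ln P(s) - ln P(o|s)]` accumulated over factors and
#' time steps, with the per-modality inaccuracy (cross-entropy of each
#' observation under the posterior predictive) reported separately.
#'
#' @inheritParams infer_states
#' @return list with `total` (nats), `complexity`, and
#'   `per_modality_per_time` (modalities x time matrix of inaccuracies).
#' @export
variational_free_energy <- function(model, beliefs, observations) {
  .free_energy(model, beliefs, observations)
}

#' Posterior predictive distribution over a factor's next state
#'
#' Applies the path-averaged transition to the most recent state posterior;
#' with no inferred steps yet, returns the initial prior `D`.
#'
#' @param beliefs a `belief_state`.
#' @param model a `gen_model`.
#' @param factor factor index.
#' @return probability vector over the factor's states.
#' @export
predictive_posterior <- function(beliefs, model, factor) {
  tcur <- ncol(beliefs$s[[factor]])
  if (tcur == 0L) return(model$D[[factor]])
  if (isTRUE(model$factors[[factor]]$controllable)) {
    act <- beliefs$actions[tcur]
    if (is.na(act) || length(act) == 0) act <- 2L
    return(as.vector(model$B[[factor]][, , act] %*% beliefs$s[[factor]][, tcur]))
  }
  as.vector(.bbar(model, beliefs, factor) %*% beliefs$s[[factor]][, tcur])
}
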