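# Episode/epoch scheduler for agent ensembles, the experiment protocols
# (sharing demo, language acquisition, transgenerational transmission,
# language emergence, supervised structure learning) and the reported
# metrics.

#' Create an agent for an ensemble
#'
#' @param model the agent's `gen_model`.
#' @param speaks whether the agent broadcasts its beliefs (a naive child
#'   listens but is not heard by the fluent agents).
#' @param gaze_copy `NA` for an agent that selects its own gaze by expected
#'   free energy, or the index of the agent whose gaze it copies (a child
#'   looking wherever its parent looks).
#' @param name label.
#' @return an `ens_agent` list.
#' @export
ens_agent <- function(model, speaks = TRUE, gaze_copy = NA_integer_,
                      name = NULL) {
  structure(list(model = model, beliefs = new_beliefs(model),
                 speaks = speaks, gaze_copy = gaze_copy,
                 name = name %||% paste0("agent", model$meta$agent_index)),
            class = "ens_agent")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialise an ensemble episode
#'
#' @param agents list of [ens_agent()].
#' @param world a `world_state` with one gaze slot per agent.
#' @param communication whether heard auditory observations are delivered.
#' @param mode likelihood message mode passed to [infer_states()].
#' @param record `"light"` (per-epoch scalars) or `"full"` (location
#'   posteriors, per-sweep traces and policy posteriors retained).
#' @return an `ensemble` state object; advance it with [run_epoch()].
#' @export
init_ensemble <- function(agents, world, communication = TRUE,
                          mode = "bound", record = "light") {
  n <- length(agents)
  obs <- replicate(n, list(), simplify = FALSE)
  structure(list(agents = agents, world = world, t = 0L,
                 communication = communication, mode = mode, record = record,
                 obs = obs, epochs = list()),
            class = "ensemble")
}

#' Advance an ensemble by one epoch
#'
#' Order of operations: (1) every speaking agent broadcasts the posterior
#' predictive distribution over each shareable factor; (2) each listener
#' hears the chorus (product of the other speakers' outputs); (3) the
#' environment generates visual and proprioceptive outcomes; (4) each agent
#' runs fixed-point state inference over the episode so far; (5) expected
#' free energy per gaze action, path/policy inference and action selection;
#' (6) the world is stepped with the selected gazes. Learning and model
#' reduction happen at the end of the episode (see [run_episode()]).
#'
#' @param ens an `ensemble` from [init_ensemble()].
#' @return the updated ensemble with a per-epoch record appended.
#' @export
run_epoch <- function(ens) {
  n <- length(ens$agents)
  t <- ens$t + 1L
  shareable <- ens$agents[[1]]$model$meta$shareable %||% integer(0)

  # (1) broadcasts
  spoken <- vector("list", length(shareable))
  if (ens$communication && length(shareable)) {
    for (k in seq_along(shareable)) {
      f <- shareable[k]
      spoken[[k]] <- lapply(seq_len(n), function(i) {
        ag <- ens$agents[[i]]
        if (!isTRUE(ag$speaks)) return(NULL)
        speak(ag$model, ag$beliefs, f)
      })
    }
  }

  # (2)-(3) observations per agent
  for (i in seq_len(n)) {
    ag <- ens$agents[[i]]
    env <- observe_environment(ens$world, i, ag$model)
    o <- vector("list", length(ag$model$modalities))
    names(o) <- vapply(ag$model$modalities, `[[`, "", "name")
    for (g in seq_along(ag$model$modalities)) {
      spec <- ag$model$modalities[[g]]
      if (spec$channel == "environmental") {
        o[[g]] <- env[[spec$name]]
      } else if (ens$communication) {
        k <- match(spec$parents[1], shareable)
        outs <- spoken[[k]]
        others <- outs[setdiff(which(!vapply(outs, is.null, logical(1))), i)]
        if (length(others)) {
          h <- Reduce(`*`, others)
          h <- pmax(h, .eps)
          o[[g]] <- h / sum(h)
        }
      }
    }
    ens$obs[[i]][[t]] <- o
  }

  # (4) inference
  for (i in seq_len(n)) {
    ag <- ens$agents[[i]]
    ag$beliefs <- infer_states(ag$model, ag$beliefs, ens$obs[[i]],
                               mode = ens$mode)
    ens$agents[[i]] <- ag
  }

  # (5) planning and action
  actions <- integer(n)
  for (i in seq_len(n)) {
    ag <- ens$agents[[i]]
    efe <- efe_all_actions(ag$model, ag$beliefs)
    ag$beliefs <- infer_paths(ag$model, ag$beliefs, efe)
    actions[i] <- select_action(ag$beliefs$policy)
    ens$agents[[i]] <- ag
  }
  for (i in seq_len(n)) {
    src <- ens$agents[[i]]$gaze_copy
    if (!is.na(src)) actions[i] <- actions[src]
    ens$agents[[i]]$beliefs$actions <-
      c(ens$agents[[i]]$beliefs$actions, actions[i])
  }

  # epoch record
  rec <- list(
    t = t,
    location = ens$world$location,
    actions = actions,
    F = vapply(ens$agents, function(a) a$beliefs$F_last, numeric(1)),
    precise_loc = vapply(ens$agents, function(a) {
      max(a$beliefs$s[[1]][, t]) >= 0.9
    }, logical(1)),
    contact = vapply(seq_len(n), function(i) {
      o <- ens$obs[[i]][[t]]
      any(o$foveal[1:3] > 0.5) || any(c(o$contrast_left[1:2],
                                        o$contrast_centre[1:2],
                                        o$contrast_right[1:2]) > 0.5)
    }, logical(1)),
    dopamine = vapply(ens$agents, function(a) -.entropy(a$beliefs$policy),
                      numeric(1)))
  if (identical(ens$record, "full")) {
    rec$s_loc <- lapply(ens$agents, function(a) a$beliefs$s[[1]][, t])
    rec$policy <- lapply(ens$agents, function(a) a$beliefs$policy)
  }
  ens$epochs[[t]] <- rec

  # (6) step the world
  ens$world <- step_world(ens$world, actions)
  ens$t <- t
  ens
}

#' Run one episode of an ensemble
#'
#' Runs `n_epochs` epochs, then (optionally) the end-of-episode learning
#' pass over each agent's learnable likelihoods using the smoothed state
#' posteriors, and (optionally) one Bayesian-model-reduction step per
#' learnable modality.
#'
#' @inheritParams init_ensemble
#' @param n_epochs episode length (8 or 16 in the shipped protocols).
#' @param learning run gated Dirichlet learning at episode end.
#' @param reduction run Bayesian model reduction after learning.
#' @param priors list (per agent) of named lists of prior counts per
#'   learnable modality, as maintained across episodes by the caller;
#'   created from the current counts when `NULL` and reduction is on.
#' @param learn_batch accumulate the episode's coincidences into one gated
#'   update instead of gating each epoch separately (default per-epoch;
#'   the emergence and supervised protocols batch).
#' @return list with updated `agents`, `world`, `priors`, the per-epoch
#'   records (`epochs`), learning and reduction diagnostics.
#' @export
run_episode <- function(agents, world, n_epochs = 8, communication = TRUE,
                        learning = FALSE, reduction = FALSE, priors = NULL,
                        mode = "bound", record = "light", learn_batch = FALSE) {
  ens <- init_ensemble(agents, world, communication, mode, record)
  for (t in seq_len(n_epochs)) ens <- run_epoch(ens)
  learn_info <- vector("list", length(agents))
  reduce_log <- vector("list", length(agents))
  if (learning) {
    for (i in seq_along(ens$agents)) {
      ag <- ens$agents[[i]]
      # full smoothing pass: learning uses the episode-converged posteriors
      ag$beliefs <- infer_states(ag$model, ag$beliefs, ens$obs[[i]],
                                 mode = mode, window = Inf)
      if (reduction) {
        learnable_i <- which(vapply(ag$model$modalities,
                                    function(g) isTRUE(g$learnable),
                                    logical(1)))
        if (length(learnable_i)) {
          if (is.null(priors)) priors <- vector("list", length(agents))
          if (is.null(priors[[i]])) {
            priors[[i]] <- stats::setNames(ag$model$A[learnable_i],
                                           as.character(learnable_i))
          }
        }
      }
      res <- .learn_episode(ag$model, ag$beliefs, ens$obs[[i]],
                            batch = learn_batch,
                            priors = if (reduction) priors[[i]] else NULL)
      ag$model <- res$model
      learn_info[[i]] <- res$info
      ens$agents[[i]] <- ag
      if (reduction && !is.null(res$info)) {
        red <- .reduce_episode(ag$model, priors[[i]])
        ens$agents[[i]]$model <- red$model
        priors[[i]] <- red$priors
        reduce_log[[i]] <- red$log
      }
    }
  }
  list(agents = ens$agents, world = ens$world, priors = priors,
       epochs = ens$epochs, obs = ens$obs,
       learn_info = learn_info, reduce_log = reduce_log)
}

# ---- metrics ---------------------------------------------------------------

#' Divergence between two likelihood mappings
#'
#' Column-wise KL divergence between the Dirichlet means, summed over
#' columns (hidden-state combinations), with floored logarithms.
#'
#' @param a1,a2 count arrays of a common shape.
#' @return non-negative divergence (nats).
#' @export
mapping_divergence <- function(a1, a2) {
  if (length(a1) != length(a2)) stop("shape mismatch", call. = FALSE)
  m1 <- dirichlet_mean(a1); m2 <- dirichlet_mean(a2)
  m1 <- .as_mat(m1); m2 <- .as_mat(m2)
  sum(m1 * (ln_eps(m1) - ln_eps(m2)))
}

#' Structural complexity increment
#'
#' Adds the Dirichlet-to-Dirichlet KL divergence between the current and
#' reference counts to a running total: the cumulative information gain due
#' to learning (an information-length approximation). Non-decreasing.
#'
#' @param current,reference count arrays (reference = the previous
#'   episode's counts).
#' @param accumulate running total to add to.
#' @return updated running total.
#' @export
structural_complexity <- function(current, reference, accumulate = 0) {
  accumulate + dirichlet_kl(current, reference)
}

#' Low-free-energy episode flag
#'
#' `TRUE` when the mean variational free energy per modality and observation
#' is below `threshold` (1 nat): the agent's observations carried negligible
#' surprisal.
#'
#' @param F_per_modality_per_epoch matrix of per-modality, per-epoch free
#'   energies (inaccuracies); `NA` entries (unobserved) are ignored.
#' @param threshold nats (default 1).
#' @return logical flag.
#' @export
low_F_incidence <- function(F_per_modality_per_epoch, threshold = 1) {
  mean(F_per_modality_per_epoch, na.rm = TRUE) < threshold
}

#' Scalar electrophysiological correlates of belief updating
#'
#' Firing rates are the recorded posterior expectations; local field
#' potentials are their first temporal difference; dopamine is the negative
#' entropy of the policy posterior per epoch (phasic responses are its
#' changes).
#'
#' @param belief_trace list with `states` (states x steps matrix of
#'   posterior expectations) and `policy` (actions x epochs matrix).
#' @return list `firing`, `lfp`, `dopamine`.
#' @export
electrophysiology <- function(belief_trace) {
  firing <- belief_trace$states
  lfp <- if (ncol(firing) > 1) t(diff(t(firing))) else firing * 0
  dopamine <- apply(belief_trace$policy, 2, function(p) -.entropy(p))
  list(firing = firing, lfp = lfp, dopamine = dopamine)
}

# mean inaccuracy per modality/observation over an episode, from the final
# (smoothed) belief state; entries without an observation are NA
.episode_acc <- function(agent, obs) {
  acc <- agent$beliefs$acc
  for (tau in seq_along(obs)) {
    for (g in seq_len(nrow(acc))) {
      if (is.null(obs[[tau]][[g]])) acc[g, tau] <- NA_real_
    }
  }
  acc
}

# ---- experiment protocols --------------------------------------------------

.sample_world <- function(n_agents) {
  init_world(sample.int(9, 1), sample.int(3, 1), sample.int(2, 1),
             sample.int(2, 1), n_agents = n_agents)
}

.fresh_beliefs <- function(agents) {
  lapply(agents, function(a) { a$beliefs <- new_beliefs(a$model); a })
}

#' Run a named experiment protocol
#'
#' * `sharing_demo`: one 8-epoch episode of three fluent sentinels with the
#'   subject starting at location 1 moving clockwise, run twice on the same
#'   hidden-state sequence — once communicating, once with silenced
#'   (uniform) auditory mappings.
#' * `acquisition`: three fluent parents plus one naive child (auditory
#'   counts uniformly one) who sees and hears alongside its parent for 32
#'   episodes of 16 epochs, learning with forgetting (`eta = 32`).
#' * `generations`: acquisition repeated, the child replacing its parent and
#'   the next parent receiving a new child, until all founders are replaced.
#' * `emergence`: three auditory-naive agents, learning and model reduction
#'   on, 512 episodes of 8 epochs with sampled initial states.
#' * `supervised`: fluent auditory mappings everywhere, agent 3 visually
#'   naive; learning and reduction on its visual modalities; `hearing`
#'   toggles the supervision (the control sets the novice's auditory counts
#'   to 64 everywhere).
#'
#' @param name experiment name.
#' @param config list of overrides (`n_episodes`, `n_epochs`, `eta`,
#'   `alpha`, `init_noise_sd`, `hearing`, ...); see [default_config()].
#' @param seed integer seed controlling initial counts and episode
#'   initial-state sampling.
#' @return a list of metrics and logs, structure depending on `name`.
#' @export
run_experiment <- function(name = c("sharing_demo", "acquisition",
                                    "generations", "emergence", "supervised"),
                           config = list(), seed = 1) {
  name <- match.arg(name)
  cfg <- utils::modifyList(default_config(name), config)
  set.seed(seed)
  switch(name,
         sharing_demo = .exp_sharing_demo(cfg),
         acquisition = .exp_acquisition(cfg),
         generations = .exp_generations(cfg),
         emergence = .exp_emergence(cfg),
         supervised = .exp_supervised(cfg))
}

#' Default experiment configurations
#'
#' Every field reproduces the shipped protocol; pass overrides through the
#' `config` argument of [run_experiment()].
#'
#' @param name experiment name.
#' @return named list of defaults.
#' @export
default_config <- function(name) {
  base <- list(eta = 32, alpha = 32, policy_precision = 16,
               init_noise_sd = 1, precision_counts = 128, gaze_shift = 2L,
               mode = "bound")
  extra <- switch(name,
    sharing_demo = list(n_epochs = 8, start_location = 1,
                        motion = "clockwise", proximity = "near",
                        pose = "foe"),
    acquisition = list(n_episodes = 32, n_epochs = 16, parent = 1L,
                       child_noise_sd = 0, learn_batch = FALSE),
    generations = list(n_episodes = 32, n_epochs = 16, parent = 1L,
                       child_noise_sd = 0, learn_batch = FALSE),
    emergence = list(n_episodes = 512, n_epochs = 16, learn_batch = TRUE),
    supervised = list(n_episodes = 512, n_epochs = 8, hearing = TRUE,
                      deaf_counts = 64, learn_batch = TRUE),
    list())
  utils::modifyList(base, extra)
}

.build_trio <- function(cfg, ...) {
  lapply(1:3, function(i) {
    build_sentinel_agent(i, init_noise_sd = cfg$init_noise_sd,
                         precision_counts = cfg$precision_counts,
                         gaze_shift = cfg$gaze_shift, eta = cfg$eta,
                         alpha = cfg$alpha,
                         policy_precision = cfg$policy_precision, ...)
  })
}

.exp_sharing_demo <- function(cfg) {
  models <- .build_trio(cfg)
  world0 <- init_world(cfg$start_location, cfg$motion, cfg$proximity,
                       cfg$pose, n_agents = 3)
  agents <- lapply(models, ens_agent)
  with_comm <- run_episode(agents, world0, n_epochs = cfg$n_epochs,
                           communication = TRUE, mode = cfg$mode,
                           record = "full")
  agents_sil <- lapply(models, function(m) ens_agent(silence(m)))
  without_comm <- run_episode(agents_sil, world0, n_epochs = cfg$n_epochs,
                              communication = TRUE, mode = cfg$mode,
                              record = "full")
  summarise <- function(run) {
    ep <- run$epochs
    list(F = t(vapply(ep, `[[`, numeric(3), "F")),
         precise = t(vapply(ep, `[[`, logical(3), "precise_loc")),
         contact = t(vapply(ep, `[[`, logical(3), "contact")),
         dopamine = t(vapply(ep, `[[`, numeric(3), "dopamine")),
         actions = t(vapply(ep, `[[`, integer(3), "actions")),
         location = vapply(ep, `[[`, numeric(1), "location"),
         s_loc = lapply(ep, `[[`, "s_loc"),
         total_F = sum(vapply(run$agents, function(a) a$beliefs$F_last,
                              numeric(1))))
  }
  first_true <- function(flags) {
    i <- which(flags)
    if (length(i)) i[1] else NA_integer_
  }
  wc <- summarise(with_comm); nc <- summarise(without_comm)
  list(with_comm = wc, without_comm = nc,
       first_precise_comm = apply(wc$precise, 2, first_true),
       first_precise_nocomm = apply(nc$precise, 2, first_true),
       first_contact_comm = apply(wc$contact, 2, first_true),
       first_contact_nocomm = apply(nc$contact, 2, first_true))
}

.exp_acquisition <- function(cfg, parents = NULL) {
  if (is.null(parents)) parents <- .build_trio(cfg)
  p <- cfg$parent
  child_model <- build_sentinel_agent(
    p, naive_auditory = TRUE, init_noise_sd = cfg$child_noise_sd,
    precision_counts = cfg$precision_counts, gaze_shift = cfg$gaze_shift,
    eta = cfg$eta, alpha = cfg$alpha,
    policy_precision = cfg$policy_precision,
    home_centre = parents[[p]]$meta$home_centre)
  agents <- c(lapply(parents, ens_agent),
              list(ens_agent(child_model, speaks = FALSE, gaze_copy = p,
                             name = "child")))
  aud <- child_model$meta$auditory
  div0 <- sum(vapply(aud, function(g) {
    mapping_divergence(child_model$A[[g]], parents[[p]]$A[[g]])
  }, numeric(1)))
  n_ep <- cfg$n_episodes
  divergence <- learning_kl <- mi_loc <- numeric(n_ep)
  F_ep <- matrix(0, n_ep, length(agents))
  for (e in seq_len(n_ep)) {
    world <- .sample_world(length(agents))
    agents <- .fresh_beliefs(agents)
    run <- run_episode(agents, world, n_epochs = cfg$n_epochs,
                       learning = TRUE, mode = cfg$mode,
                       learn_batch = cfg$learn_batch)
    agents <- run$agents
    child <- agents[[4]]$model
    divergence[e] <- sum(vapply(aud, function(g) {
      mapping_divergence(child$A[[g]], parents[[p]]$A[[g]])
    }, numeric(1)))
    li <- run$learn_info[[4]]
    learning_kl[e] <- if (is.null(li)) 0 else li$learning_kl
    mi_loc[e] <- joint_mutual_information(child$A[[aud[1]]])
    F_ep[e, ] <- vapply(agents, function(a) a$beliefs$F_last, numeric(1)) /
      cfg$n_epochs
  }
  list(divergence = divergence, divergence0 = div0,
       learning_kl = learning_kl, mi_location = mi_loc, F_episode = F_ep,
       child = agents[[4]]$model, parents = lapply(agents[1:3], `[[`, "model"))
}

.exp_generations <- function(cfg) {
  founders <- .build_trio(cfg)
  parents <- founders
  phases <- vector("list", 3)
  for (p in 1:3) {
    cfg$parent <- p
    res <- .exp_acquisition(cfg, parents = parents)
    child <- res$child
    # the matured child replaces its parent; its mappings are frozen
    for (g in child$meta$auditory) child$modalities[[g]]$learnable <- FALSE
    child <- refresh_model(child)
    parents[[p]] <- child
    phases[[p]] <- res
  }
  final_div <- vapply(1:3, function(i) {
    sum(vapply(founders[[i]]$meta$auditory, function(g) {
      mapping_divergence(parents[[i]]$A[[g]], founders[[i]]$A[[g]])
    }, numeric(1)))
  }, numeric(1))
  list(phases = phases, final = parents, founders = founders,
       final_divergence = final_div)
}

.exp_emergence <- function(cfg) {
  agents <- lapply(.build_trio(cfg, naive_auditory = TRUE), ens_agent)
  aud_loc <- agents[[1]]$model$meta$auditory[1]
  n_ep <- cfg$n_episodes
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  pair_kl <- matrix(0, n_ep, 3)
  mi <- matrix(0, n_ep, 3)
  F_ep <- matrix(0, n_ep, 3)
  lowF <- matrix(FALSE, n_ep, 3)
  complexity <- matrix(0, n_ep, 3)
  comp_run <- numeric(3)
  prev_counts <- lapply(agents, function(a) a$model$A[[aud_loc]])
  priors <- NULL
  for (e in seq_len(n_ep)) {
    world <- .sample_world(3)
    agents <- .fresh_beliefs(agents)
    run <- run_episode(agents, world, n_epochs = cfg$n_epochs,
                       learning = TRUE, reduction = TRUE, priors = priors,
                       mode = cfg$mode, learn_batch = cfg$learn_batch)
    agents <- run$agents
    priors <- run$priors
    for (k in 1:3) {
      pr <- pairs[[k]]
      pair_kl[e, k] <- mapping_divergence(
        agents[[pr[1]]]$model$A[[aud_loc]],
        agents[[pr[2]]]$model$A[[aud_loc]]) / 9
    }
    for (i in 1:3) {
      mi[e, i] <- joint_mutual_information(agents[[i]]$model$A[[aud_loc]])
      F_ep[e, i] <- agents[[i]]$beliefs$F_last / cfg$n_epochs
      lowF[e, i] <- low_F_incidence(.episode_acc(agents[[i]], run$obs[[i]]))
      comp_run[i] <- structural_complexity(agents[[i]]$model$A[[aud_loc]],
                                           prev_counts[[i]], comp_run[i])
      complexity[e, i] <- comp_run[i]
      prev_counts[[i]] <- agents[[i]]$model$A[[aud_loc]]
    }
  }
  list(pair_kl = pair_kl, mi = mi, F_episode = F_ep, low_F = lowF,
       complexity = complexity, agents = lapply(agents, `[[`, "model"))
}

.exp_supervised <- function(cfg) {
  models <- list(
    build_sentinel_agent(1, precision_counts = cfg$precision_counts,
                         gaze_shift = cfg$gaze_shift, eta = cfg$eta,
                         alpha = cfg$alpha,
                         policy_precision = cfg$policy_precision),
    build_sentinel_agent(2, precision_counts = cfg$precision_counts,
                         gaze_shift = cfg$gaze_shift, eta = cfg$eta,
                         alpha = cfg$alpha,
                         policy_precision = cfg$policy_precision),
    build_sentinel_agent(3, naive_visual = TRUE,
                         init_noise_sd = cfg$init_noise_sd,
                         precision_counts = cfg$precision_counts,
                         gaze_shift = cfg$gaze_shift, eta = cfg$eta,
                         alpha = cfg$alpha,
                         policy_precision = cfg$policy_precision,
                         uniform_auditory_counts =
                           if (cfg$hearing) NULL else cfg$deaf_counts))
  agents <- lapply(models, ens_agent)
  n_ep <- cfg$n_episodes
  F_ep <- matrix(0, n_ep, 3)
  lowF <- matrix(FALSE, n_ep, 3)
  complexity <- numeric(n_ep)
  comp_run <- 0
  vis <- models[[3]]$meta$visual
  prev_counts <- models[[3]]$A[vis]
  priors <- NULL
  for (e in seq_len(n_ep)) {
    world <- .sample_world(3)
    agents <- .fresh_beliefs(agents)
    run <- run_episode(agents, world, n_epochs = cfg$n_epochs,
                       learning = TRUE, reduction = TRUE, priors = priors,
                       mode = cfg$mode, learn_batch = cfg$learn_batch)
    agents <- run$agents
    priors <- run$priors
    for (i in 1:3) {
      F_ep[e, i] <- agents[[i]]$beliefs$F_last / cfg$n_epochs
      lowF[e, i] <- low_F_incidence(.episode_acc(agents[[i]], run$obs[[i]]))
    }
    cur <- agents[[3]]$model$A[vis]
    for (k in seq_along(vis)) {
      comp_run <- structural_complexity(cur[[k]], prev_counts[[k]], comp_run)
    }
    complexity[e] <- comp_run
    prev_counts <- cur
  }
  list(F_episode = F_ep, low_F = lowF, complexity = complexity,
       convergence_episode = supervision_convergence(F_ep),
       novice = agents[[3]]$model)
}

#' Episode at which a novice's inference matches its supervisors
#'
#' Episode-mean free energies vary strongly with how informative an episode
#' happens to be, so both traces are smoothed with a trailing `run_length`-
#' episode mean; convergence is the start of the first run of `run_length`
#' consecutive smoothed episodes in which the novice sits within `tol`
#' (relative, with a one-nat comparison floor) of the supervisors' mean.
#'
#' @param F_episode episodes x agents matrix; the last column is the novice.
#' @param tol relative tolerance (default 0.1).
#' @param run_length smoothing window and required consecutive episodes
#'   (default 8).
#' @return episode index, or `NA` if never reached.
#' @export
supervision_convergence <- function(F_episode, tol = 0.1, run_length = 8) {
  roll <- function(x) stats::filter(x, rep(1 / run_length, run_length),
                                    sides = 1)
  sup <- roll(rowMeans(F_episode[, -ncol(F_episode), drop = FALSE]))
  nov <- roll(F_episode[, ncol(F_episode)])
  ok <- abs(nov - sup) <= tol * pmax(abs(sup), 1)
  ok[is.na(ok)] <- FALSE
  run <- 0
  for (e in seq_along(ok)) {
    run <- if (ok[e]) run + 1 else 0
    if (run >= run_length) return(e - run_length + 1L)
  }
  NA_integer_
}

#' Episode from which pairwise mapping divergence stays below a bound
#'
#' @param pair_kl episodes x pairs matrix of per-column mapping KL.
#' @param threshold nats per column (default 0.1).
#' @return first episode index after which the row mean stays below
#'   `threshold` through the end of the run, or `NA`.
#' @export
convergence_episode <- function(pair_kl, threshold = 0.1) {
  m <- rowMeans(pair_kl)
  below <- rev(cumprod(rev(m < threshold))) > 0
  i <- which(below)
  if (length(i)) i[1] else NA_integer_
}
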