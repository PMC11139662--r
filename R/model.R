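# Generative model specification and the sentinel world.
#
# A generative model is a discrete POMDP: likelihood tensors A (Dirichlet
# counts, outcome axis first), per-factor transition tensors B (state x state
# x path), path-transition matrices C, initial-state priors D, initial-path
# priors E and outcome-preference counts c. The sentinel world has three
# agents on a 9-location circle watching a subject; each agent has four
# hidden-state factors and eight outcome modalities.

#' Declare a hidden-state factor
#'
#' @param name label.
#' @param n_states number of levels (>= 1).
#' @param n_paths number of paths (dynamics) for this factor.
#' @param controllable whether the agent selects this factor's path by acting;
#'   only permitted when `n_paths > 1`.
#' @return a `factor_spec` list.
#' @export
factor_spec <- function(name, n_states, n_paths = 1, controllable = FALSE) {
  stopifnot(n_states >= 1, n_paths >= 1)
  if (controllable && n_paths <= 1) {
    stop("controllable factors need more than one path", call. = FALSE)
  }
  structure(list(name = name, n_states = as.integer(n_states),
                 n_paths = as.integer(n_paths), controllable = controllable),
            class = "factor_spec")
}

#' Declare an outcome modality
#'
#' @param name label.
#' @param n_outcomes number of outcome levels.
#' @param parents integer indices of the parent factors (order fixes the
#'   parent axes of the likelihood tensor).
#' @param channel `"environmental"` (outcomes generated by the world) or
#'   `"communicative"` (outcomes generated by other agents' beliefs);
#'   communicative modalities have exactly one parent, the shared factor.
#' @param learnable whether the Dirichlet counts of this modality are updated
#'   by active learning.
#' @return a `modality_spec` list.
#' @export
modality_spec <- function(name, n_outcomes, parents,
                          channel = c("environmental", "communicative"),
                          learnable = FALSE) {
  channel <- match.arg(channel)
  if (!length(parents)) stop("parents must be non-empty", call. = FALSE)
  if (channel == "communicative" && length(parents) != 1) {
    stop("communicative modalities have exactly one parent", call. = FALSE)
  }
  structure(list(name = name, n_outcomes = as.integer(n_outcomes),
                 parents = as.integer(parents), channel = channel,
                 learnable = learnable),
            class = "modality_spec")
}

#' Assemble a generative model
#'
#' Validates shapes and normalisation: every B path slice has unit column
#' sums, D and E are normalised, A counts are strictly positive.
#'
#' @param factors list of [factor_spec()].
#' @param modalities list of [modality_spec()].
#' @param A list of Dirichlet count arrays, one per modality (outcome axis
#'   first, parent axes in declared order).
#' @param B list per factor of `state x state x path` transition arrays.
#' @param C list per factor of `path x path` path-transition matrices.
#' @param D,E lists of initial state / path priors per factor.
#' @param c_pref list of outcome-preference count vectors per modality
#'   (defaults to flat).
#' @param alpha expected-free-energy precision gating learning and selection.
#' @param eta forgetting hyperprior: total Dirichlet counts saturate at `eta`.
#' @param policy_precision precision of the policy softmax.
#' @param meta free-form list (agent index, world geometry, ...).
#' @return object of class `gen_model`.
#' @export
gen_model <- function(factors, modalities, A, B, C = NULL, D = NULL, E = NULL,
                      c_pref = NULL, alpha = 8, eta = 32,
                      policy_precision = 16, meta = list()) {
  nf <- length(factors); ng <- length(modalities)
  stopifnot(length(A) == ng, length(B) == nf)
  if (is.null(C)) C <- lapply(factors, function(f) diag(f$n_paths))
  if (is.null(D)) D <- lapply(factors, function(f) rep(1 / f$n_states, f$n_states))
  if (is.null(E)) E <- lapply(factors, function(f) rep(1 / f$n_paths, f$n_paths))
  if (is.null(c_pref)) c_pref <- lapply(modalities, function(g) rep(1, g$n_outcomes))
  m <- structure(list(factors = factors, modalities = modalities,
                      A = A, B = B, C = C, D = D, E = E, c_pref = c_pref,
                      alpha = alpha, eta = eta,
                      policy_precision = policy_precision, meta = meta),
                 class = "gen_model")
  validate_model(m)
  # structural caches (independent of the counts)
  m$children <- lapply(seq_len(nf), function(f) {
    which(vapply(modalities, function(g) f %in% g$parents, logical(1)))
  })
  refresh_model(m)
}

#' Validate a generative model's invariants
#' @param m a `gen_model`.
#' @return invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_model <- function(m) {
  nf <- length(m$factors)
  for (f in seq_len(nf)) {
    fs <- m$factors[[f]]
    B <- m$B[[f]]
    if (!identical(dim(B), c(fs$n_states, fs$n_states, fs$n_paths))) {
      stop("B[[", f, "]] has wrong shape", call. = FALSE)
    }
    cs <- apply(B, 3, colSums)
    if (any(abs(cs - 1) > 1e-9)) {
      stop("B[[", f, "]] columns must sum to 1 per path", call. = FALSE)
    }
    if (abs(sum(m$D[[f]]) - 1) > 1e-9 || abs(sum(m$E[[f]]) - 1) > 1e-9) {
      stop("D and E must be normalised for factor ", f, call. = FALSE)
    }
  }
  for (g in seq_along(m$modalities)) {
    gs <- m$modalities[[g]]
    a <- m$A[[g]]
    want <- c(gs$n_outcomes, vapply(m$factors[gs$parents],
                                    function(x) x$n_states, integer(1)))
    d <- dim(a); if (is.null(d)) d <- length(a)
    if (!identical(as.integer(d), as.integer(want))) {
      stop("A[[", g, "]] has wrong shape", call. = FALSE)
    }
    .check_counts(a, paste0("A[[", g, "]]"))
  }
  invisible(TRUE)
}

#' @export
print.gen_model <- function(x, ...) {
  cat("<gen_model>", length(x$factors), "factors,",
      length(x$modalities), "modalities\n")
  for (f in x$factors) {
    cat(sprintf("  factor  %-10s %d states, %d paths%s\n", f$name, f$n_states,
                f$n_paths, if (f$controllable) " (controllable)" else ""))
  }
  for (g in x$modalities) {
    cat(sprintf("  modality %-18s %d outcomes <- {%s}%s%s\n", g$name,
                g$n_outcomes, paste(g$parents, collapse = ","),
                if (g$channel == "communicative") " [communicative]" else "",
                if (g$learnable) " [learnable]" else ""))
  }
  invisible(x)
}

# ---- message-passing cache -------------------------------------------------

# Precompute, per modality: column-normalised mean, log mean, digamma tensor,
# matricisations per parent factor (other axes x target axis), conditional
# outcome entropies and novelty weights per parent combination. Rebuilt
# whenever counts change (refresh_model).

#' Rebuild the cached likelihood statistics of a model
#'
#' Must be called after directly mutating count tensors; all package
#' functions that modify counts call it themselves.
#'
#' @param m a `gen_model`.
#' @return the model with an up-to-date cache.
#' @export
refresh_model <- function(m) {
  cache <- vector("list", length(m$modalities))
  for (g in seq_along(m$modalities)) {
    a <- m$A[[g]]
    d <- dim(a); if (is.null(d)) d <- length(a)
    mean_a <- dirichlet_mean(a)
    phi_a <- expected_log(a)
    k <- length(d)
    per_parent_mean <- vector("list", k - 1)
    per_parent_phi <- vector("list", k - 1)
    if (k > 1) {
      for (ax in 2:k) {
        perm <- c(setdiff(seq_len(k), ax), ax)
        per_parent_mean[[ax - 1]] <- matrix(aperm(mean_a, perm), ncol = d[ax])
        per_parent_phi[[ax - 1]] <- matrix(aperm(phi_a, perm), ncol = d[ax])
      }
    }
    mm <- .as_mat(mean_a)
    ln_mm <- ln_eps(mm)
    H_cond <- -colSums(mm * ln_mm)        # conditional outcome entropy per combo
    am <- .as_mat(a)
    W <- 0.5 * (1 / am - rep(1 / colSums(am), each = nrow(am)))
    nov <- colSums(mm * W)                # novelty weight per parent combo
    cache[[g]] <- list(mean = mean_a, mean_mat = mm, ln_mean_mat = ln_mm,
                       pp_mean = per_parent_mean, pp_phi = per_parent_phi,
                       H_cond = H_cond, novelty_w = nov)
  }
  m$cache <- cache
  m
}

# weight vector for contracting modality g against all parents except `skip`
# (skip = 0 keeps all parents). dists: list of per-factor posteriors.
.parent_weight <- function(spec, dists, skip = 0L) {
  ps <- spec$parents
  vs <- dists[ps]
  if (skip > 0L) vs <- vs[ps != skip]
  if (!length(vs)) return(1)
  Reduce(function(x, y) as.vector(outer(x, y)), vs)
}

# ---- the sentinel world ----------------------------------------------------

.wrap9 <- function(x) ((x - 1) %% 9) + 1

# field-of-view geometry: agent home centres 120 degrees apart; gaze ahead
# puts the fovea on the home centre, gaze left/right shifts it by -/+ shift
# times the agent's orientation (the rotational direction its leftward
# glance sweeps); the window is fovea +/- 1.
.fovea <- function(centre, gaze, shift = 2L, orientation = 1L) {
  .wrap9(centre + orientation * shift * (gaze - 2L))
}

.window <- function(centre, gaze, shift = 2L, orientation = 1L) {
  f <- .fovea(centre, gaze, shift, orientation)
  .wrap9(c(f - 1L, f, f + 1L))
}

.det_counts <- function(map, precision = 128, eps = 1 / 16) {
  precision * map + eps
}

.naive_counts <- function(dims, sd = 1) {
  n <- prod(dims)
  a <- 1 + abs(stats::rnorm(n, 0, sd))
  array(a, dim = dims)
}

#' Build one sentinel agent's generative model
#'
#' Four factors: subject `location` (9 states; paths still/clockwise/
#' anticlockwise), `proximity` (close/near, single path), `pose` (friend/foe,
#' single path), and the agent's own `gaze` (left/ahead/right; three
#' controllable paths that set the gaze directly). Eight modalities: a foveal
#' classifier (friend/foe/someone/none), three contrast-energy detectors
#' (close/near/none) over the left/centre/right window slots, proprioceptive
#' gaze, and three auditory channels with identity maps onto location,
#' proximity and pose (the shareable factors).
#'
#' @param agent_index 1, 2 or 3; fixes the home centre (locations 2, 5, 8).
#' @param naive_auditory replace the auditory likelihood counts by
#'   `1 + |N(0, init_noise_sd)|` and mark them learnable.
#' @param naive_visual same for the four visual modalities.
#' @param uniform_auditory_counts if non-`NULL`, set every auditory count to
#'   this constant (an agent that neither produces nor understands speech).
#' @param init_noise_sd scale of the unsigned Gaussian added to naive counts.
#' @param precision_counts count scale of known deterministic likelihoods.
#' @param gaze_shift foveal shift (in locations) for looking left/right.
#' @param orientation +1 or -1: the rotational direction swept by a leftward
#'   glance. The default assignment (+1, -1, +1) gives the ensemble
#'   complementary search patterns.
#' @param eta,alpha,policy_precision model hyperparameters.
#' @param home_centre override the home centre location.
#' @return a `gen_model` for this agent.
#' @export
build_sentinel_agent <- function(agent_index,
                                 naive_auditory = FALSE,
                                 naive_visual = FALSE,
                                 uniform_auditory_counts = NULL,
                                 init_noise_sd = 1,
                                 precision_counts = 128,
                                 gaze_shift = 2L,
                                 eta = 32, alpha = 32, policy_precision = 16,
                                 home_centre = NULL, orientation = NULL) {
  if (!agent_index %in% 1:3) stop("agent_index must be 1, 2 or 3", call. = FALSE)
  centre <- if (is.null(home_centre)) c(2L, 5L, 8L)[agent_index] else as.integer(home_centre)
  if (is.null(orientation)) orientation <- c(1L, -1L, 1L)[agent_index]

  factors <- list(
    factor_spec("location", 9, 3),
    factor_spec("proximity", 2),
    factor_spec("pose", 2),
    factor_spec("gaze", 3, 3, controllable = TRUE))

  modalities <- list(
    modality_spec("foveal", 4, c(1L, 2L, 3L, 4L)),
    modality_spec("contrast_left", 3, c(1L, 2L, 4L)),
    modality_spec("contrast_centre", 3, c(1L, 2L, 4L)),
    modality_spec("contrast_right", 3, c(1L, 2L, 4L)),
    modality_spec("proprioceptive", 3, 4L),
    modality_spec("aud_location", 9, 1L, channel = "communicative"),
    modality_spec("aud_proximity", 2, 2L, channel = "communicative"),
    modality_spec("aud_pose", 2, 3L, channel = "communicative"))

  # deterministic maps
  fov <- array(0, c(4, 9, 2, 2, 3))
  for (g in 1:3) {
    fv <- .fovea(centre, g, gaze_shift, orientation)
    for (l in 1:9) for (p in 1:2) for (q in 1:2) {
      o <- if (l == fv) { if (p == 1L) q else 3L } else 4L
      fov[o, l, p, q, g] <- 1
    }
  }
  contrast <- lapply(1:3, function(slot) {
    ar <- array(0, c(3, 9, 2, 3))
    for (g in 1:3) {
      w <- .window(centre, g, gaze_shift, orientation)[slot]
      for (l in 1:9) for (p in 1:2) {
        o <- if (l == w) p else 3L
        ar[o, l, p, g] <- 1
      }
    }
    ar
  })
  prop <- array(diag(3), c(3, 3))
  aud <- list(array(diag(9), c(9, 9)), array(diag(2), c(2, 2)),
              array(diag(2), c(2, 2)))

  A <- c(list(.det_counts(fov, precision_counts)),
         lapply(contrast, .det_counts, precision = precision_counts),
         list(.det_counts(prop, precision_counts)),
         lapply(aud, .det_counts, precision = precision_counts))

  if (naive_visual) {
    for (g in 1:4) {
      A[[g]] <- .naive_counts(dim(A[[g]]), init_noise_sd)
      modalities[[g]]$learnable <- TRUE
    }
  }
  if (naive_auditory) {
    for (g in 6:8) {
      A[[g]] <- .naive_counts(dim(A[[g]]), init_noise_sd)
      modalities[[g]]$learnable <- TRUE
    }
  }
  if (!is.null(uniform_auditory_counts)) {
    stopifnot(uniform_auditory_counts > 0)
    for (g in 6:8) {
      A[[g]] <- array(uniform_auditory_counts, dim(A[[g]]))
      modalities[[g]]$learnable <- FALSE
    }
  }

  # transitions: still / clockwise / anticlockwise for location
  Bloc <- array(0, c(9, 9, 3))
  Bloc[, , 1] <- diag(9)
  for (j in 1:9) {
    Bloc[.wrap9(j + 1), j, 2] <- 1
    Bloc[.wrap9(j - 1), j, 3] <- 1
  }
  Bgaze <- array(0, c(3, 3, 3))
  for (u in 1:3) Bgaze[u, , u] <- 1   # action u sets gaze to u
  B <- list(Bloc, array(diag(2), c(2, 2, 1)), array(diag(2), c(2, 2, 1)), Bgaze)

  D <- list(rep(1 / 9, 9), rep(0.5, 2), rep(0.5, 2), c(0, 1, 0))
  # weak prior preference for gazing straight ahead breaks planning ties
  E <- list(rep(1 / 3, 3), 1, 1, c(0.3, 0.4, 0.3))

  gen_model(factors, modalities, A, B, D = D, E = E,
            alpha = alpha, eta = eta, policy_precision = policy_precision,
            meta = list(agent_index = agent_index, home_centre = centre,
                        gaze_shift = as.integer(gaze_shift),
                        orientation = as.integer(orientation),
                        shareable = 1:3, auditory = 6:8, visual = 1:4,
                        precision_counts = precision_counts))
}

#' Initialise the sentinel world state
#'
#' @param start_location 1..9.
#' @param motion `"still"`, `"clockwise"` or `"anticlockwise"` (or 1..3).
#' @param proximity `"close"` or `"near"` (or 1..2).
#' @param pose `"friend"` or `"foe"` (or 1..2).
#' @param n_agents number of observers (gaze starts `ahead` for all).
#' @return a `world_state` list.
#' @export
init_world <- function(start_location, motion = "still", proximity = "near",
                       pose = "friend", n_agents = 3) {
  loc <- as.integer(start_location)
  if (is.na(loc) || loc < 1 || loc > 9) stop("location must be 1..9", call. = FALSE)
  dec <- function(x, levels) {
    if (is.character(x)) x <- match(x, levels)
    x <- as.integer(x)
    if (is.na(x) || x < 1 || x > length(levels)) {
      stop("invalid level; expected one of ", paste(levels, collapse = "/"),
           call. = FALSE)
    }
    x
  }
  structure(list(location = loc,
                 proximity = dec(proximity, c("close", "near")),
                 pose = dec(pose, c("friend", "foe")),
                 motion = dec(motion, c("still", "clockwise", "anticlockwise")),
                 gaze = rep(2L, n_agents)),
            class = "world_state")
}

#' Advance the world one epoch
#'
#' The subject moves along its path (clockwise = +1 on the 1-based cyclic
#' labels); proximity and pose are static within an episode; the agents'
#' gazes are set to the supplied actions.
#'
#' @param w a `world_state`.
#' @param gazes integer vector of gaze actions (1 left, 2 ahead, 3 right),
#'   one per agent; `NULL` leaves gazes unchanged.
#' @return updated `world_state`.
#' @export
step_world <- function(w, gazes = NULL) {
  w$location <- switch(w$motion, w$location,
                       .wrap9(w$location + 1L), .wrap9(w$location - 1L))
  if (!is.null(gazes)) w$gaze <- as.integer(gazes)
  w
}

#' Generate one agent's environmental observations
#'
#' Deterministic visual geometry: the gaze-dependent window covers three
#' contiguous locations; the foveal modality reports friend/foe if the
#' subject sits on the foveal slot and is close, "someone" if near, else
#' "none"; each contrast modality reports the subject's proximity if the
#' subject occupies that slot; proprioception reports gaze exactly.
#'
#' @param w a `world_state`.
#' @param agent_index which agent observes.
#' @param model that agent's `gen_model` (supplies geometry).
#' @return named list of one-hot observation vectors for the five
#'   environmental modalities.
#' @export
observe_environment <- function(w, agent_index, model) {
  centre <- model$meta$home_centre
  shift <- model$meta$gaze_shift
  ori <- model$meta$orientation %||% 1L
  g <- w$gaze[agent_index]
  win <- .window(centre, g, shift, ori)
  fv <- win[2]
  onehot <- function(i, n) { v <- numeric(n); v[i] <- 1; v }
  fov_o <- if (w$location == fv) {
    if (w$proximity == 1L) w$pose else 3L
  } else 4L
  contr <- lapply(1:3, function(slot) {
    onehot(if (w$location == win[slot]) w$proximity else 3L, 3)
  })
  list(foveal = onehot(fov_o, 4),
       contrast_left = contr[[1]], contrast_centre = contr[[2]],
       contrast_right = contr[[3]],
       proprioceptive = onehot(g, 3))
}
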