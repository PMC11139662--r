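# Bayesian model reduction over Dirichlet priors and active model
# selection: gradient-proposed reduced priors, scored analytically with
# ratios of Beta functions, accepted by a softmax of the free-energy
# difference and blended by Bayesian model averaging.

#' Free-energy change of a reduced Dirichlet prior
#'
#' `dF = lnB(posterior) + lnB(reduced_prior) - lnB(prior) -
#' lnB(posterior + reduced_prior - prior)`; negative values favour the
#' reduced model. Equals the difference in log marginal likelihood of the
#' implied count data under the two priors.
#'
#' @param posterior,prior,reduced_prior strictly positive count arrays of a
#'   common shape.
#' @return scalar free-energy change (nats).
#' @export
reduction_delta_F <- function(posterior, prior, reduced_prior) {
  implied <- posterior + reduced_prior - prior
  if (any(implied <= 0)) {
    stop("reduction invalid: implied posterior has non-positive counts",
         call. = FALSE)
  }
  log_beta(posterior) + log_beta(reduced_prior) -
    log_beta(prior) - log_beta(implied)
}

# gradient of G(a) = -MI - cost with respect to the counts a
# (chain rule through the joint normalisation)
.efe_param_grad <- function(a, c_counts = NULL) {
  s <- sum(a)
  abar <- a / s
  d <- dim(abar); if (is.null(d)) d <- length(abar)
  m <- .as_mat(abar)
  po <- rowSums(m)
  ps <- colSums(m)
  g_abar <- 1 - ln_eps(abar) + array(ln_eps(outer(po, ps)), dim = d)
  if (!is.null(c_counts)) {
    # preference gradient: -phi(c) broadcast over the outcome axis
    phi <- .pref_log(c_counts)
    d <- dim(a); if (is.null(d)) d <- length(a)
    idx <- slice.index(array(0, dim = d), 1)
    g_abar <- g_abar - array(phi[idx], dim = d)
  }
  (g_abar - sum(abar * g_abar)) / s
}

#' Propose a reduced prior along the expected-free-energy gradient
#'
#' Multiplicative update in log-count space,
#' `a_hat = a * exp(-lambda * a * dG/da)`, with `lambda` scaled so the
#' first-order predicted decrease in `G` equals `step` nats. Sharpens
#' informative associations and shrinks uninformative ones while keeping all
#' counts strictly positive.
#'
#' @param current count array to propose from (typically posterior counts).
#' @param c_counts preference counts over outcomes (default flat).
#' @param step predicted expected-free-energy decrease in nats (default 1).
#' @param scope `"joint"` takes one global step; `"column"` distributes
#'   the step over columns and renormalises each column to its current
#'   total, so hidden-state combinations commit to their outcome
#'   associations independently instead of competing for mass across
#'   columns.
#' @return proposed count array.
#' @export
propose_prior <- function(current, c_counts = NULL, step = 1,
                          scope = c("joint", "column")) {
  .check_counts(current)
  scope <- match.arg(scope)
  g <- .efe_param_grad(current, c_counts)
  h <- current * g          # gradient with respect to ln(a)
  if (scope == "joint") {
    denom <- sum(h^2)
    if (denom <= 0) return(current)
    lambda <- step / denom
    # parameter EFE is scale invariant, so the log-count step is clipped to
    # keep the (gauge) magnitude of individual counts bounded
    return(current * exp(pmin(pmax(-lambda * h, -16), 16)))
  }
  cm <- .as_mat(current)
  hm <- .as_mat(h)
  out <- cm
  step_c <- step / ncol(cm)
  for (j in seq_len(ncol(cm))) {
    denom <- sum(hm[, j]^2)
    if (denom <= 0) next
    lambda <- step_c / denom
    v <- cm[, j] * exp(pmin(pmax(-lambda * hm[, j], -16), 16))
    out[, j] <- v * (sum(cm[, j]) / sum(v))
  }
  array(out, dim = dim(current) %||% length(current))
}

#' Active model selection over a proposed reduced prior
#'
#' Scores the proposal with [reduction_delta_F()], accepts it with
#' probability `softmax(-alpha * c(0, dF))[2]`, blends old prior and
#' proposal by Bayesian model averaging, and adjusts the posterior so the
#' data counts `posterior - prior` are preserved.
#'
#' @param posterior,prior current posterior and prior count arrays.
#' @param proposal proposed reduced prior (e.g. from [propose_prior()]).
#' @param alpha selection precision.
#' @return list `new_prior`, `new_posterior`, `accept_prob`, `delta_F`.
#' @export
active_select <- function(posterior, prior, proposal, alpha = 8) {
  implied <- posterior + proposal - prior
  if (any(implied <= 0)) {
    return(list(new_prior = prior, new_posterior = posterior,
                accept_prob = 0, delta_F = NA_real_, valid = FALSE))
  }
  dF <- reduction_delta_F(posterior, prior, proposal)
  p <- .softmax(-alpha * c(0, dF))[2]
  new_prior <- (1 - p) * prior + p * proposal
  new_posterior <- posterior + (new_prior - prior)
  list(new_prior = new_prior, new_posterior = new_posterior,
       accept_prob = p, delta_F = dF, valid = TRUE)
}

#' One Bayesian-model-reduction step for a likelihood's counts
#'
#' Proposes a reduced prior along the parameter expected-free-energy
#' gradient (evaluated at the posterior counts, where the learned structure
#' lives). The default `"column"` scope exploits the exact additivity of
#' the log-Beta evidence over columns: every hidden-state combination
#' proposes its own one-step reduction (rescaled to its prior column mass)
#' and is accepted or rejected on its own evidence, with a per-column trust
#' region that halves the step while the evidence overwhelmingly rejects
#' it. `"joint"` proposes and scores one global reduction.
#'
#' @param posterior,prior current posterior and prior count arrays.
#' @param c_counts preference counts (default flat).
#' @param alpha selection precision.
#' @param step initial predicted expected-free-energy decrease (nats).
#' @param max_backoff maximum number of step halvings before giving up.
#' @param scope `"column"` (default) or `"joint"`.
#' @return list `new_prior`, `new_posterior`, `accept_prob` (mean committed
#'   acceptance over columns for the column scope), `delta_F`
#'   (acceptance-weighted total), `valid`.
#' @export
bmr_step <- function(posterior, prior, c_counts = NULL, alpha = 8,
                     step = 1, max_backoff = 8, scope = "column") {
  if (identical(scope, "joint")) {
    lam <- step
    for (k in seq_len(max_backoff)) {
      prop <- propose_prior(posterior, c_counts, step = lam, scope = "joint")
      prop <- prop * (sum(prior) / sum(prop))
      if (all(posterior + prop - prior > 0)) {
        sel <- active_select(posterior, prior, prop, alpha = alpha)
        if (sel$accept_prob >= 0.05 || k == max_backoff) return(sel)
      }
      lam <- lam / 2
    }
    return(list(new_prior = prior, new_posterior = posterior,
                accept_prob = 0, delta_F = NA_real_, valid = FALSE))
  }
  # column-factorised selection: the log-Beta evidence is exactly additive
  # over columns, so every hidden-state combination proposes its own
  # reduction and is accepted or rejected on its own evidence
  pm <- .as_mat(posterior)
  prm <- .as_mat(prior)
  g <- .efe_param_grad(posterior, c_counts)
  hm <- .as_mat(posterior * g)
  new_prior <- prm
  dF_tot <- 0
  acc <- numeric(ncol(pm))
  score <- function(j, lam) {
    v <- pm[, j] * exp(pmin(pmax(-(lam / sum(hm[, j]^2)) * hm[, j], -16), 16))
    v <- v * (sum(prm[, j]) / sum(v))
    if (!all(pm[, j] + v - prm[, j] > 0)) return(NULL)
    dF <- log_beta(matrix(pm[, j])) + log_beta(matrix(v)) -
      log_beta(matrix(prm[, j])) -
      log_beta(matrix(pm[, j] + v - prm[, j]))
    list(v = v, dF = dF, p = .softmax(-alpha * c(0, dF))[2])
  }
  for (j in seq_len(ncol(pm))) {
    # no evidence, no reduction: with no data counts in this column the
    # evidence cannot arbitrate (dF = 0) and averaging would merely commit
    # amplified prior noise
    if (sum(pm[, j] - prm[, j]) < 1) next
    if (sum(hm[, j]^2) <= 0) next
    lam <- step
    best <- NULL
    for (k in seq_len(max_backoff)) {
      cand <- score(j, lam)
      if (!is.null(cand) && (cand$p >= 0.05 || k == max_backoff)) {
        best <- cand
        break
      }
      lam <- lam / 2
    }
    if (is.null(best)) next
    # trust-region escalation: while the evidence strongly accepts the
    # reduction, deepen it
    while (best$p >= 0.95 && lam < step * 1024) {
      lam <- lam * 2
      cand <- score(j, lam)
      if (is.null(cand) || cand$p < 0.95) break
      best <- cand
    }
    new_prior[, j] <- (1 - best$p) * prm[, j] + best$p * best$v
    dF_tot <- dF_tot + best$p * best$dF
    acc[j] <- best$p
  }
  d <- dim(posterior); if (is.null(d)) d <- length(posterior)
  np <- array(new_prior, dim = d)
  list(new_prior = np,
       new_posterior = posterior + (np - array(prm, dim = d)),
       accept_prob = mean(acc), delta_F = dF_tot, valid = TRUE)
}

# end-of-episode reduction pass over the learnable modalities of one agent.
# `priors` is a named list (by modality index as character) of prior counts.
.reduce_episode <- function(model, priors, step = NULL) {
  if (is.null(step)) step <- model$meta$bmr_step %||% 1
  learnable <- which(vapply(model$modalities, function(g) isTRUE(g$learnable),
                            logical(1)))
  log <- list()
  for (g in learnable) {
    key <- as.character(g)
    prior <- priors[[key]]
    posterior <- model$A[[g]]
    sel <- bmr_step(posterior, prior, alpha = model$alpha, step = step)
    priors[[key]] <- sel$new_prior
    model$A[[g]] <- sel$new_posterior
    log[[model$modalities[[g]]$name]] <-
      list(delta_F = sel$delta_F, accept_prob = sel$accept_prob,
           sparsity = mean(sel$new_posterior < 1.5))
  }
  model <- refresh_model(model)
  list(model = model, priors = priors, log = log)
}
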