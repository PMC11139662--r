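# The communication channel: speakers map their posterior predictive
# beliefs through the mean auditory likelihood into an outcome distribution
# ("word"); listeners hear the normalised product of all other speakers'
# outputs (sensory attenuation excludes an agent's own broadcast). Words are
# soft observations: they carry both the content and the confidence of the
# broadcast beliefs.

#' Speak: broadcast beliefs about one shareable factor
#'
#' The speaker's auditory-outcome distribution is the mean auditory
#' likelihood applied to the posterior predictive distribution over the
#' factor, normalised by the speaker's own ignorance baseline — the output
#' it would produce under a uniform predictive. The word therefore carries
#' the evidence the speaker's beliefs add over its ignorance: a fully
#' uncertain speaker is quiet (exactly uniform), and a mapping's global
#' outcome bias (which says nothing about the state) is never broadcast.
#' For a balanced likelihood — identity or any permutation, as in the
#' fluent sentinels — the baseline is uniform and the word is the plain
#' likelihood-mapped belief.
#'
#' @param model the speaker's `gen_model`.
#' @param beliefs the speaker's `belief_state`.
#' @param factor shareable factor index (location, proximity or pose).
#' @return probability vector over the auditory outcome levels.
#' @export
speak <- function(model, beliefs, factor) {
  g <- .aud_modality(model, factor)
  pred <- predictive_posterior(beliefs, model, factor)
  mm <- model$cache[[g]]$mean_mat
  w <- as.vector(mm %*% pred)
  base <- rowMeans(mm)
  w <- pmax(w, .eps) / pmax(base, .eps)
  w / sum(w)
}

.aud_modality <- function(model, factor) {
  for (g in seq_along(model$modalities)) {
    spec <- model$modalities[[g]]
    if (spec$channel == "communicative" && spec$parents[1] == factor) return(g)
  }
  stop("no auditory modality for factor ", factor, call. = FALSE)
}

#' Chorus: the heard mixture of other agents' broadcasts
#'
#' Normalised element-wise product (product of experts, the log-sum of the
#' communication message) of all speakers' output distributions excluding
#' the listener's own. A flat speaker is inert under the product; a single
#' confident speaker dominates.
#'
#' @param speaker_outputs list of probability vectors, one per agent.
#' @param listener_index index whose own output is excluded (sensory
#'   attenuation); use 0 for an agent that does not speak.
#' @param mode `"product"` (default, the log-sum reading) or `"mixture"`
#'   (average of the speakers' outputs).
#' @return probability vector; uniform (with a warning attribute) if no
#'   other speakers exist.
#' @export
chorus <- function(speaker_outputs, listener_index,
                   mode = c("product", "mixture")) {
  mode <- match.arg(mode)
  others <- speaker_outputs[setdiff(seq_along(speaker_outputs), listener_index)]
  if (!length(others)) {
    n <- length(speaker_outputs[[1]])
    out <- rep(1 / n, n)
    attr(out, "empty") <- TRUE
    return(out)
  }
  if (mode == "mixture") {
    out <- Reduce(`+`, others) / length(others)
    return(out / sum(out))
  }
  out <- Reduce(`*`, others)
  out <- pmax(out, .eps)
  out / sum(out)
}

#' Silence a model's communication channel
#'
#' Returns a copy whose auditory likelihood counts are uniform (equal
#' counts), so heard input carries no information and spoken output is
#' uniform. Idempotent.
#'
#' @param model a `gen_model` with auditory modalities.
#' @param counts the uniform count value (default 1).
#' @return the silenced `gen_model`.
#' @export
silence <- function(model, counts = 1) {
  found <- FALSE
  for (g in seq_along(model$modalities)) {
    if (model$modalities[[g]]$channel == "communicative") {
      model$A[[g]] <- array(counts, dim = dim(model$A[[g]]))
      found <- TRUE
    }
  }
  if (!found) stop("model has no communicative modalities", call. = FALSE)
  refresh_model(model)
}
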