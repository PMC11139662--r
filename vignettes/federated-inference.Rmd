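---
title: "Federated inference and belief sharing: models and methods"
author: "fedinf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated inference and belief sharing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fedinf` simulates ensembles of discrete-state active-inference agents that
share beliefs by broadcasting them through a communicative outcome channel.
This vignette records the models, the numerical choices, and the design
decisions behind the package — the things a maintainer would want to know
before changing a default.

## The generative model

Each agent owns a discrete partially observed Markov decision process
(POMDP). Hidden states are factorised: factor $f$ has $S_f$ levels and
$U_f$ paths (dynamics). Outcomes are factorised into modalities: modality
$g$ has $O_g$ levels and a set of parent factors. The tensors are

* $A^g$ — likelihood Dirichlet counts, outcome axis first, one parent axis
  per parent factor in declared order;
* $B^f$ — state-transition array ($S_f \times S_f \times U_f$), columns
  normalised per path slice;
* $C^f$ — path transitions (identity here: a path persists within an
  episode);
* $D^f$, $E^f$ — initial state and path priors;
* $c^g$ — outcome-preference counts (flat in every shipped protocol).

Perception minimises variational free energy
$F = \mathbb{E}_Q[\ln Q(s) - \ln P(s) - \ln P(o \mid s)]$; planning scores
each action $u$ by expected free energy
$G(u) = \underbrace{D_{KL}[Q(o \mid u)\,\|\,P(o \mid c)]}_{\text{risk}}
      + \underbrace{\mathbb{E}_{Q}[H[P(o \mid s)]]}_{\text{ambiguity}}
      - \underbrace{\text{novelty}}_{\text{Dirichlet info gain}}$,
and parameters are scored by
$G(a) = -I(o; s \mid a) - \mathbb{E}[\ln P(o \mid c)]$ — the negative
mutual information of the joint distribution the counts encode, minus an
expected cost that vanishes for flat preferences.

## The sentinel world

Three agents sit back-to-back at home centres 2, 5 and 8 of a 9-location
circle, watching a subject that is `still`, `clockwise` or `anticlockwise`
(one step per 250 ms epoch), `close` or `near`, and a `friend` or a `foe`.
Four factors per agent: subject location (9 states, 3 paths), proximity
(2, static), pose (2, static), own gaze (3 states, 3 controllable paths
that set the gaze directly). Eight modalities: a foveal classifier
(friend/foe/someone/none — friend vs foe only when the subject is close
and on the foveal slot), three contrast-energy detectors (close/near/none)
over the three window slots, proprioceptive gaze, and three auditory
channels with identity maps onto the shareable factors (location,
proximity, pose).

Geometry. Gazing ahead puts the fovea on the home centre; the visual
window is fovea ± 1. Looking left or right shifts the fovea by two
locations, so each agent reaches seven contiguous locations, and the three
reachable arcs jointly cover the circle. Two geometric parameters are not
derivable from first principles and were fixed by the printed behaviour of
the ensemble (the first epochs at which the second and third sentinels can
see a clockwise subject starting at location 1, namely 3 and 5):

* the gaze shift of ±2 (a ±1 shift cannot produce a first contact at
  epoch 5 for the third agent);
* the per-agent *orientation* — the rotational direction a leftward glance
  sweeps, default `(+1, -1, +1)`. Agents 2 and 3 occupy mirror-image
  positions relative to the subject's start, and under any shared
  deterministic gaze rule their search patterns are mirror images, which
  makes the printed contact epochs jointly unattainable; opposite
  handedness for agent 2 gives the ensemble a complementary search pattern
  and reproduces them. Both parameters are exposed in
  `build_sentinel_agent()`.

Known deterministic likelihoods are encoded as Dirichlet counts
`128 * map + 1/16`: effectively precise, strictly positive, and still
ordinary count tensors. The prior over gaze paths is `E = (0.3, 0.4, 0.3)`
— a weak (0.29 nat) preference for looking straight ahead that breaks
expected-free-energy ties (all agents start gazing ahead) without
overriding genuine epistemic gradients, which are an order of magnitude
larger when the agents are uncertain.

## Inference: fixed-point sweeps

State posteriors satisfy
$s_\tau^f = \sigma(\text{likelihood messages} + \text{forward} +
\text{backward})$, swept over all epochs of the episode so far until the
free-energy change falls below 1/128 nats or 16 sweeps are exhausted
(non-convergence is recorded, not an error). Numerical choices:

* Likelihood messages default to the Jensen bound
  $\ln(o \odot \mu(a) \odot s_{\setminus f})$, which exploits sparse
  likelihood tensors; the exact Dirichlet expectation (digamma form) is
  available as `mode = "digamma"` and used in tests.
* Temporal messages propagate the *path-averaged transition in probability
  space*: forward $\ln(\bar{B} s_{\tau-1})$, backward through the
  row-normalised transpose of $\bar{B}$. The alternative — averaging
  elementwise logarithms of near-deterministic slices — couples the floored
  $\ln$ values (−32) into the sweep and collapses diffuse posteriors into
  spurious point estimates; the probability-space form is also what the
  field's reference implementations use.
* Beliefs about uncontrolled factors propagate through a *volatility
  hedge*: the path-averaged transition is mixed with a uniform jump at
  $\kappa = 1/32$. Deterministic transitions otherwise carry exact zeros
  whose floored logarithms lock the mean-field sweeps into dynamically
  inconsistent minima: an agent that once mis-commits (say, "standing
  still at location 7") could never be moved by any amount of later
  contradicting evidence, because relocating costs 32 nats. The hedge
  prices an escape at about 6 nats — overridable by one confident
  contradicting observation — while correct tracking costs only
  $\ln(1-\kappa) \approx 0.03$ nats per step. The world process itself
  remains deterministic.
* Each call re-sweeps the trailing 8 time steps (earlier posteriors and
  their cached accuracy terms are frozen); a full smoothing pass over the
  whole episode runs once before learning. For 8-epoch episodes this is
  exactly the full scheme; for 16-epoch episodes it reduces the cost from
  quadratic to linear in episode length.
* Expected free energies are snapped to a $10^{-6}$-nat grid before the
  policy softmax, so actions whose values differ only by floating-point
  residue are genuine ties, decided by the `E` prior and the lowest-index
  rule rather than rounding noise.
* All logarithms are floored at $\varepsilon = e^{-32}$; all information
  quantities are in nats.
* Uncontrolled multi-path posteriors (the subject's unseen motion) are
  re-estimated online each sweep from the transition likelihood of the
  inferred state sequence.
* Policies are depth-1: one epoch of look-ahead, matching the one-step
  predictive structure of the planning objective.
* Action selection is argmax with lowest-index tie-break; seeded sampling
  is available.

## Communication

Speakers broadcast the posterior *predictive* distribution over each
shareable factor (beliefs formed before the current epoch's observations),
mapped through their mean auditory likelihood and normalised by the
speaker's *ignorance baseline* — the output it would produce under a
uniform predictive. A "word" is therefore a probability distribution that
carries the evidence the speaker's beliefs add over its ignorance:
confidence as well as content. The baseline matters only for unbalanced
(naive) mappings: without it, an uncertain naive speaker emits its
likelihood's row means — a state-independent bias that every listener
imprints coherently into every column of its own mapping, and the
emergent lexicon collapses to a single word. With it, ignorance is
exactly quiet, and for identity or permutation mappings (whose baseline
is uniform) the word is the plain likelihood-mapped belief, preserving
the exact one-round consensus fixed point. Listeners hear the normalised
element-wise product of all other speakers' outputs (a product of
experts, the log-sum form of the communication message); an agent never
hears itself (sensory attenuation prevents double-counting). A
mixture-of-experts chorus is available behind `mode = "mixture"` for
ablations. Silencing a model sets its auditory counts uniform: it can
neither produce nor recognise informative words.

One exchange round among agents with identity mappings leaves every agent
with the same posterior — the normalised product of all the priors, the
fixed point of the joint free energy. Iterating rounds over a static world
re-assimilates reflected evidence (each agent's prior returns via the
others' broadcasts) and slowly polarises; the consensus property is
therefore a single-round property, which is how the test suite asserts it.

## Learning with forgetting

At the end of each episode (using the smoothed, episode-converged
posteriors) every learnable modality receives gated updates built from
the coincidences $\Delta a = o \otimes_{i} s^i_\tau$ (unit mass per
observation), committed with probability
$\sigma(-\alpha [G(a), G(a + \Delta a)])$ and followed by the decay
$a \leftarrow (a + p\,\Delta a)\,\eta / (\eta + p\,\Sigma\Delta a)$,
whose fixed point keeps the accumulated counts at $\eta$. Defaults:
$\eta = 32$ (the last ~32 observations dominate — young, impressionable
agents) and $\alpha = 32$.

Two granularities are used, matched to the learning problem:

* *Per observation* (acquisition, transmission): each epoch's unit
  coincidence is gated on its own. Learning from fluent teachers is a
  high signal-to-noise problem in which the one systematically
  uninformative coincidence per episode — the epoch-1 word, flat because
  predictions start at the uniform initial prior — must be individually
  rejectable. At $\alpha = 32$ the gate is decisively selective at the
  single-count scale and the child's mappings converge to the teachers'
  with no flat residue (at $\alpha = 8$, the spec of a Bayesian model
  average, ~40% of flat words commit and the child-parent divergence
  plateaus around 8% of its initial value).
* *Batched per episode* (emergence, supervised structure learning): the
  episode's coincidences are summed (the Einstein summation over time of
  the learning update) and gated once. When structure must emerge from
  weak correlations, single coincidences never move whole-tensor mutual
  information measurably and per-observation gating reduces to a coin
  flip; the batch gives the gate a macroscopic quantity to judge.

The gate precision $\alpha$ has no published value; $\alpha = 32$ puts
single-count increments on an $\eta$-saturated tensor in the
near-selection regime the learning rule is described by. Substantially
larger values over-select (rarely visited hidden states never accumulate
evidence); smaller ones under-select.

## Structure learning

After learning, each learnable modality takes one Bayesian-model-reduction
step. Reduced priors are proposed multiplicatively in log-count space
along the negative gradient of the parameter expected free energy, scored
analytically with the log-Beta form of the model evidence change, and
blended by Bayesian model averaging through
$\sigma(-\alpha[0, \Delta F])$, with the posterior adjusted so the data
counts are preserved. The bookkeeping that makes this behave:

* The consolidated prior persists across episodes, and forgetting applies
  to the accumulated *data* counts only, so that posterior = prior + data
  throughout and the reduction algebra stays coherent (joint decay drives
  the prior's mass to zero and reduces the scheme to plain learning;
  decaying the posterior beneath a persistent prior makes every reduction
  permanently infeasible). The prior is the agent's long-term structural
  memory — selected associations carry counts well above $\eta$, immune
  to the volatility forgetting that churns the data counts.
* $G(a)$ is scale invariant, so the gradient leaves total count mass
  unconstrained (a gauge direction): proposals are rescaled to the
  prior's mass — a reduced prior redistributes evidence rather than
  inventing it.
* Selection factorises over columns: the log-Beta evidence is exactly
  additive over the columns of a likelihood tensor, so every hidden-state
  combination proposes its own reduction (rescaled to its prior column
  mass) and is accepted or rejected on its own evidence. A jointly
  normalised proposal instead makes columns compete for mass and
  amplifies the degenerate rank-1 (one-word) structure; and for wide
  visual tensors the per-column pace is what lets a hundred-column
  mapping consolidate in reasonable time.
* A per-column trust region halves the 1-nat step while the evidence
  overwhelmingly rejects the proposal, and columns holding less than one
  full observation of evidence are skipped entirely — with no data the
  evidence cannot arbitrate ($\Delta F = 0$) and averaging would merely
  commit amplified prior noise as confident false structure.

The gradient is evaluated at the posterior counts: at a near-uniform
prior the mutual-information gradient vanishes, so proposing from the
prior can never start the sparsification; the learned structure lives in
the posterior.

## Experiment protocols and problem sizes

All experiments are fully synthetic; episode initial states (location,
motion, proximity, pose) are sampled uniformly under seed control where the
protocol varies them.

* `sharing_demo` — one 8-epoch episode, subject clockwise from location 1,
  run with and without communication on the same hidden-state sequence
  (~1 s). "Precise belief" is operationalised as ≥ 0.9 posterior mass.
* `acquisition` — 3 fluent parents plus a naive child (auditory counts
  uniformly 1) that sees through its parent's eyes and hears all parents;
  32 episodes × 16 epochs.
* `generations` — acquisition repeated, each matured child replacing its
  parent (mappings frozen), until all founders are replaced.
* `emergence` — 3 auditory-naive agents (counts $1 + |\mathcal{N}(0,1)|$),
  learning + reduction, 512 episodes × 16 epochs (the acquisition episode
  length, which the emergence protocol repeats; with 8-epoch episodes the
  fraction of mutually informed coincidences is too small and the
  emergent mapping's mutual information plateaus well short of two nats).
* `supervised` — fluent ensemble, agent 3 visually naive; learning +
  reduction on its four visual modalities; the unsupervised control sets
  its auditory counts to 64 everywhere. 512 episodes × 8 epochs.
  Convergence is judged on episode-mean free energy smoothed with a
  trailing 8-episode mean (raw episode means vary with how informative an
  episode happens to be), within 10% of the supervisors for 8 consecutive
  episodes.

`scripts/acceptance.R` re-runs acquisition at full size (three seeds) and
emergence and supervised structure learning over 256-episode horizons:
their reported quantities are first-crossing episode indices that occur
within the first few dozen episodes, and the remaining ~230 episodes
demonstrate that the crossings persist.

## What the generator does and does not emulate

The world process is deterministic given its initial state: visual
observations are exact functions of geometry, and the only stochasticity
is in initial conditions and naive-count initialisation. Real perceptual
channels are noisy, real ensembles are asynchronous, and real "words" are
discrete tokens rather than transmitted sufficient statistics; passing
tests therefore demonstrate the *mechanics* of federated inference —
belief sharing, gated learning, reduction — not robustness to sensor noise
or token-level language. Turn-taking, agency attribution, hierarchical
(temporal) depth, habit learning and moving agents are out of scope.

## Known limitations

* Mean-field state posteriors cannot represent correlated uncertainty
  across epochs; with deterministic transitions this shows up as
  over-confident interpolation when evidence is sparse.
* An informed agent with flat preferences has no expected-information-gain
  reason to fixate a subject it is already certain about; visual tracking
  of a known target would require non-flat preferences or residual model
  uncertainty.
* The consensus property degrades under indefinitely repeated exchange
  over a static world (reflected-evidence double counting); predictive
  broadcasts over a changing world, as in the sentinel protocols, do not
  suffer from this in practice.
* Emergent lexicons are permutation-like but may merge world states that
  are observationally hard to separate (neighbouring locations), capping
  the mapping's mutual information slightly below $\ln 9$.
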