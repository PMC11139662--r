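# fedinf

Federated active inference and belief sharing in ensembles of
discrete-state agents.

## What this package is for

How can agents with complementary, partial views of a shared world pool
what they know — and where does the code they pool it in come from?
`fedinf` simulates ensembles of active-inference agents, each a discrete
partially observed Markov decision process (POMDP), that broadcast their
posterior predictive beliefs through a communicative outcome channel and
assimilate each other's broadcasts as soft observations. Perception,
action, learning and structure learning are all cast as free-energy
minimisation:

* **Inference** — state posteriors by variational message passing:
  `s_tau = softmax(likelihood messages + forward + backward)`, iterated to
  a fixed point.
* **Planning** — actions scored by expected free energy
  `G(u) = risk + ambiguity − novelty`; with flat outcome preferences this
  is pure expected information gain.
* **Learning** — likelihood Dirichlet counts accumulate observed
  state–outcome coincidences `Δa = o ⊗ s`, committed with probability
  `σ(−α·G(a|u))` (the expected-free-energy gate, `G(a) = −I(o;s) − cost`)
  and forgotten at rate `η/(η+1)` so that totals saturate at `η`.
* **Selection** — Bayesian model reduction over Dirichlet priors:
  gradient-proposed reduced priors, scored analytically by log-Beta
  ratios (`ΔF = lnB(a) + lnB(a') − lnB(a) − lnB(a + a' − a)`), accepted
  through `σ(−α·ΔF)` and blended by Bayesian model averaging.

The package ships the three-sentinel surveillance world — three watchers
with ~120° fields of view monitoring a subject on a 9-location circle —
and the four experiment protocols built on it: a belief-sharing
demonstration, language acquisition by a naive child, transgenerational
transmission, de novo language emergence, and supervised structure
learning. It is aimed at computational neuroscientists and students of
multi-agent active inference who want a tested, pure-R reference
implementation of these mechanics.

## A worked example

One episode of the belief-sharing demonstration: the subject starts at
location 1 and circles clockwise past the three sentinels for eight
250-ms epochs; the same hidden-state sequence is run with and without
communication.

```r
library(fedinf)
demo <- run_experiment("sharing_demo", seed = 1)

demo$first_precise_nocomm
#> [1] 1 3 5
demo$first_precise_comm
#> [1] 1 3 3
demo$first_contact_nocomm
#> [1] 1 3 5
round(c(demo$with_comm$total_F, demo$without_comm$total_F), 1)
#> [1] 81.7 98.6
```

Reading this: searching on their own (no communication), the sentinels
first *see* the subject at epochs 1, 3 and 5 — their windows cover
complementary arcs — and each becomes certain (≥ 0.9 posterior mass) of
the subject's location only upon contact. With communication, the third
sentinel commits to the first one's broadcast and is certain by epoch 3,
two epochs before anything enters its own field of view; the ensemble's
total variational free energy drops from 98.6 to 81.7 nats.

Language acquisition by a naive child (auditory Dirichlet counts
uniformly one) listening to three fluent parents:

```r
acq <- run_experiment("acquisition", seed = 7)
round(acq$divergence0, 1)            # child-parent mapping KL, episode 0
#> [1] 53.7
which(acq$divergence < 0.05 * acq$divergence0)[1]
#> [1] 17
round(acq$mi_location[32], 2)        # MI of the learned location mapping
#> [1] 2.08
```

The summed child–parent mapping divergence falls below 5% of its initial
value by episode 17 of 32, and the learned location mapping carries
about 2.1 nats of mutual information — a near-identity map acquired
purely by gated coincidence counting.

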