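---
title: "A latent-cause belief network account of Pavlovian-instrumental transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A latent-cause belief network account of Pavlovian-instrumental transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitsbn)
```

## The phenomenon

In the two-lever Pavlovian-instrumental transfer (PIT) paradigm a rat
first learns that three sounds predict three different foods (Pavlovian
phase), then learns to press two levers for two of those foods under a
probabilistic random-ratio schedule (instrumental phase). At test, one
lever is available in extinction while sounds are played. Responding is
elevated when the sound predicts the same food as the lever (**specific
PIT**) and when it predicts the food never earned instrumentally
(**general PIT**), but *not* when it predicts the other lever's food
(**PIT inhibition**), and satiety abolishes general but not specific PIT.

`pitsbn` implements a computational account in which all three effects
fall out of goal-directed action evaluation over a learned generative
model of the conditioning chamber. The agent explains its binary
observations — sounds S1-S3, levers L1-L2, foods F1-F3, and its own
pressing A — with five binary latent causes: H1-H3 generate the
Pavlovian sound-food pairs, H4 and H5 generate each lever and modulate
both instrumental foods, and A influences F1 and F2 only. The structure
is fixed; learning estimates only the link weights.

## The generative model

Each node is Bernoulli with success probability
$\sigma(b + \sum_{\text{active parents}} w)$, where $\sigma$ is the
logistic function, $b$ the node's bias (background log-odds) and $w$ the
weight on the edge from each active parent. Latent causes are
independent Bernoulli per trial bin with prior probability
$\sigma(b_H)$; trials are independent given the weights. The marginal
likelihood of a trial sums over all $2^5 = 32$ latent configurations
exactly (the action node is additionally marginalized if it is
unobserved while one of its children is observed); unobserved nodes
contribute a factor of one. Exact enumeration keeps the likelihood
deterministic, which both enables a brute-force oracle in the test suite
and spares the sampler any latent-state augmentation. Identical trial
bins are aggregated into a multiplicity count first — the likelihood is
bit-identical and evaluation cost drops from a thousand bins to about a
dozen distinct patterns.

Weight learning targets the posterior $p(w \mid d) \propto p(d \mid w)\,
p(w)$ with independent zero-centered Gaussian priors on the link weights
(scale 6 by default): before training, the agent holds no belief about
how causes or actions shape the world.

## Biases are structural constants, not learned parameters

The single most consequential design choice in this package is that node
biases are, by default, *fixed* class-specific constants
(`background_biases()`): sounds and levers at $-8$, foods at $-2.5$,
latent causes at $-3$, the action at $0$. Only the 14 edge weights are
sampled. Three findings from the package's own development forced this:

1. **Relabeling symmetry.** If a child's bias is free, flipping a latent
   cause's meaning (active $\leftrightarrow$ inactive) maps
   $(b_H, w, b_{child}) \to (-b_H, -w, b_{child} + w)$ with *identical*
   likelihood. For rare events the flipped mode has the smaller
   $|b_{child}|$, hence the higher prior density, so a sampler on the
   free-bias posterior converges to networks in which every Pavlovian
   weight is negative — a perfectly valid relabeling, but not the
   interpretable solution in which a cause is on exactly when its
   observables occur. Clamping the biases removes the symmetry outright.

2. **Suppressor modes.** Free biases also admit solutions in which a
   latent cause switches "on" in the background and uses negative
   weights to explain the *absence* of its observables. A fixed, rare
   latent prior ($\sigma(-3) \approx 0.05$, the base rate of a Pavlovian
   episode in the training set) makes such always-on causes pay an
   unaffordable per-bin prior cost.

3. **The inhibition budget.** Writing the different-condition food
   prediction in log-odds gives the identity
   $\text{logit}\,P(F_2 \mid \text{different}, do(A{=}1)) = s_P + s_L - b_F$,
   where $s_P$ is the learned logit of the Pavlovian food rate
   ($b_F + w_{H_2 F_2}$), and $s_L$ the learned logit of the food rate
   during the other lever's press bins ($b_F + w_{A F_2} + w_{H_4 F_2}$).
   Both $s_P$ and $s_L$ are pinned by data, so the food background
   $b_F$ alone decides whether inhibition can cancel the Pavlovian
   excitation. A freely learned $b_F$ sinks to about $-7$ under the mass
   of food-absent bins, which inflates $w_{H_2 F_2}$ to compensate and
   leaves inhibition unreachable; at the fixed $-2.5$, food is expected
   enough that its absence during the wrong lever's training is
   informative, and the cross-context weight learns the deep negative
   value that PIT inhibition requires.

Sounds and levers are experimenter-controlled and essentially never occur
spontaneously, hence the very deep $-8$. This has a second, crucial
consequence: a sound forces its latent cause on in *every* bin the sound
appears, including reinforcement-omission bins, so the learned
sound-food weight is capped at the empirical pairing rate instead of
escaping toward the prior ceiling. Learning the biases remains available
(`fit_posterior(fixed = NULL)`, with a latent-bias prior centered at
$-2$ to break the relabeling symmetry), but the defaults above are what
reproduce the behavioral pattern.

## The synthetic paradigm

`paradigm_config()` encodes the study conditions. Time is discretized
into trial bins; every observable is coded present/absent in each bin.

| parameter | default | units | rationale |
|---|---|---|---|
| `n_pavlovian_per_cs` | 100 | bins | typical multi-session Pavlovian training; with pairing 0.85 it yields ~15 omission bins per sound, enough to pin the learned expectation tightly |
| `pavlovian_pairing_prob` | 0.85 | prob. | reliable but probabilistic pairing; a deterministic pairing leaves the cue-food weight prior-limited rather than data-limited, and its wide posterior upper tail bleeds into the different-condition prediction |
| `n_instrumental_per_lever` | 400 | bins | RR20 training runs to hundreds of presses per lever; also sets the depth of the learnable cross-inhibition |
| `press_prob` | 0.5 | prob. | press and no-press bins in comparable number identify the action-outcome contingency; with near-constant pressing the action's effect is confounded with its context's |
| `reinforce_prob` | 0.05 | prob. | RR20 modeled as per-press reward probability 1/20 |
| `n_blank` | 100 | bins | all-absent inter-trial bins |
| `cross_food_leak` | 0 | prob. | probability the other lever's food appears in a session bin; nonzero values emulate levers sharing context |

The generator is seeded and bit-reproducible. What it deliberately does
*not* emulate: within-session learning curves, response latencies or
magazine behavior, interval schedules, continuous stimulus intensity,
and any temporal structure across bins (latent causes are drawn i.i.d.
per bin). Passing tests therefore show that the *computational* account
is coherent under idealized binary evidence, not that it fits any
particular animal's data.

## Inference

`fit_posterior()` runs blocked random-walk Metropolis: each free
parameter in turn receives a Gaussian proposal, accepted by the exact
marginal log-posterior (computed in C++; a per-node lookup table over
latent-parent patterns avoids re-evaluating the logistic for all 32
configurations). Proposal scales adapt every 50 sweeps during burn-in
toward 30% acceptance and are frozen afterward. Two chains run by
default (15,000 sweeps, 5,000 burn-in, thinning 5) from the prior-mean
initialization, with draws pooled for reporting;
`convergence_diagnostics()` computes split-chain R-hat (threshold 1.1)
and an initial-positive-sequence effective sample size. On the default
paradigm the 14-weight posterior mixes well (R-hat < 1.05, ESS in the
thousands) in roughly ten seconds.

Correctness is checked two independent ways in the test suite: the
likelihood and the latent posterior against brute-force enumeration (to
1e-10 over randomized networks), and the sampler's moments against
fine-grid numerical integration on a one-latent toy model (mean within
0.05, sd within 10%).

## Action evaluation: context, efficacy, utility

At test, `test_evidence()` builds the extinction trial: lever and sound
states observed, foods unobserved, and the action *clamped*, never
inferred — pressing is the option under evaluation, an intervention, so
it cannot serve as evidence about the latents. The exact latent
posterior given the evidence implements the **context** principle: the
visible lever demands its instrumental cause, the sound its Pavlovian
cause, and everything else stays off.

- **Efficacy** `E` is the posterior-predictive probability of the
  lever's own food with the action on — the probability the action
  reaches its goal. It reads no utilities, which is why specific PIT
  survives devaluation exactly (bit-identical `E` under any utility
  vector).
- **Utility** `U` is the value-weighted sum of the *other* foods'
  predicted probabilities under the action: rewards that are added to
  the predicted scene motivate responding regardless of the action's
  own goal. Satiety (`utility_vector(spec, 0)`) sends `U` to zero, and
  with it general PIT.
- The **response score** is `R = alpha*E + beta*U` with both gains 1 by
  default — the minimal combination that preserves the decomposition.
  The model makes no claim about absolute press rates; PIT effects are
  reported as `R(condition) - R(baseline)`.

"Different ≈ baseline" is operationalized as an absolute effect below
0.25 of the smaller of the two positive effects (configurable in the
tests). Under continuous reinforcement the baseline efficacy saturates,
so "no specific PIT" is operationalized as an effect below 20% of its
RR20 value; logistic saturation leaves tiny residuals that a strict zero
would miscount.

## What the trained network looks like

Positive weights connect each Pavlovian cause to its sound (about +12,
a near-deterministic link against the $-8$ background) and food (about
+4, the logit gap from $-2.5$ to the 85% pairing rate); each
instrumental cause to its lever (about +15); and the action to both
instrumental foods (about +3-4, identified by the press/no-press
contrast). The instrumental causes acquire deep negative weights to the
*other* lever's food (about $-9$): during L1 training, pressing happens
hundreds of times and F2 never follows, which is informative precisely
because the action weight and the food background would otherwise
predict it. That learned exclusion is PIT inhibition waiting to happen:
in the different condition the Pavlovian excitation (+4) meets the
context's inhibition and the action's boost and still lands far below
zero.

## Numerical choices and degenerate inputs

Logistic log-probabilities use the stable `log1p(exp(...))` form; the
32-term marginalization accumulates in log space. Parameter update order
is the canonical sort of parameter names, fixing the sweep and all CSV
column orders. An empty trial collection is legal and returns the prior.
Non-finite weights, invalid probabilities, observed-food predictions,
unknown condition labels and short chains raise immediate errors.
Multiplicity compression groups on states *and* phase tag, so phase
labels survive round trips even though the likelihood ignores them.

All randomness descends from user-supplied integer seeds: the generator
consumes one stream, each MCMC chain runs under `seed + chain`, and the
pipeline helpers derive per-run seeds by fixed offsets; RNG state is
always restored, so library calls never disturb the caller's stream.

## Problem sizes

The packaged defaults — 300 Pavlovian bins, 800 instrumental bins, 200
blanks, two chains of 15,000 sweeps — fit in about ten seconds because
the compressed likelihood sees only ~13 distinct bin patterns. The test
suite's replicated end-to-end checks (20 seeds for sign recovery and the
battery pattern) and the schedule/context sweeps complete in a few
minutes on one core. These sizes are the package's chosen operating
point; everything scales through the configuration objects.

## Known limitations

The model is goal-directed only: habitual responding, and with it the
single-lever/interval-schedule literature, is out of scope. Utilities
enter only through the additional-reward term, so the overall baseline
suppression that sated animals show is not reproduced — only the
selective loss of general PIT. Devaluation is modeled as value zeroing
(satiety), not conditioned aversion. Whether a cue predicting a larger
quantity of the *same* food could drive general PIT is left unmodeled,
as is any mapping from response scores to physical press rates.
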