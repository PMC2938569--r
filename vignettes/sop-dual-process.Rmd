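---
title: "A dual-process habituation model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-process habituation model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sopdual)
```

## The model

Each stimulus is represented by a large pool of memory elements. At any
discrete moment an element is inactive (I), in the primary activity state
(A1), or in the secondary activity state (A2); `sopdual` tracks the
*proportions* `pI`, `pA1`, `pA2`, which is exact in the infinite-pool limit
of the element-level stochastic process (the test suite verifies agreement
with a 100,000-element Monte-Carlo simulation to within three binomial
standard errors).

Per moment, and per stimulus, four things happen in a fixed order:

1. **Decay.** A proportion `pd1` of A1 transfers to A2 (self-generated
   priming) and a proportion `pd2` of the *pre-transfer* A2 returns to I.
2. **Activation.** If the stimulus is present, a proportion `intensity` of
   the inactive pool enters A1. Elements in A2 cannot re-enter A1; this is
   the mechanism of habituation.
3. **Retrieval-generated priming.** Each target stimulus receives priming at
   rate `r = min(1, Σ pA1(predictor) · max(V_net, 0))` summed over its
   incoming links; `r · pI` transfers from I directly to A2. Links with
   non-positive net strength contribute nothing.
4. **Learning.** For every enabled ordered pair, `ΔV⁺ = l_excit · pA1(pred)
   · pA1(targ)` and `ΔV⁻ = l_inhib · pA1(pred) · pA2(targ)` (the opponent
   rule). Both components only ever grow; there is no extinction rule in
   scope, so `V_net = V⁺ − V⁻` can fall only through the inhibitory term.

States are recorded after all four sub-steps. This order makes a single
presentation from rest yield `pA1 = intensity` exactly, and lets same-moment
predictor activity drive priming, which the one-moment novelty test
requires. After each moment the three proportions are clipped to `[0, 1]`
and the sub-machine-epsilon residual is folded into the row's largest
component, so `pI + pA1 + pA2 = 1` holds to 1e-12 at every recorded moment.

### Parameters

| parameter   | meaning                              | default | units |
|-------------|--------------------------------------|---------|-------|
| `intensity` | I→A1 recruitment while present       | 0.2     | proportion/moment |
| `pd1`       | A1→A2 decay (self-generated priming) | 0.2     | proportion/moment |
| `pd2`       | A2→I decay                           | 0.04    | proportion/moment |
| `l_excit`   | excitatory learning rate             | 0.07    | 1/moment |
| `l_inhib`   | inhibitory learning rate             | 0.014   | 1/moment |

The defaults are the wild-type condition of the analysis; the modelled
GluA1 knockout is `pd1 = 0.11`, a 45% reduction. "Moment" is the model's
abstract time unit; all rates are per moment and nothing in the analysis
depends on a mapping to seconds.

The retrieval-priming rate above is the simplest monotone rule consistent
with associative activation entering A2 directly: linear in the summed
drive, capped at 1 so it remains a proportion. The inhibitory rule
(`pA1(pred) · pA2(targ)`) is the standard "sometimes opponent" convention.
Learning operates only on explicitly enabled ordered pairs; the novelty
paradigm enables the context (CS) as predictor of each goal stimulus (US),
which is the associative structure of the assay being modelled. Learning
remains enabled during the test trial; under the sub-step order it cannot
affect the same-moment score.

## The novelty-preference paradigm

The Y-maze assay is mapped onto three stimuli: `cs` ≈ Start-arm/context
cues, active throughout every trial; `us_trained` ≈ Sample-arm cues, active
at the end of each exposure trial; `us_novel` ≈ Novel-arm cues, present
nowhere before the test. A condition is two exposure trials (10-moment CS,
5-moment co-terminating US), a training ITI of 5 (massed) or 100 (spaced)
moments, a test interval of 5 or 100 moments, and a test of 6 CS moments
with both USs present on the final moment. The novelty-preference score is
`pA1(us_novel) − pA1(us_trained)` at that final moment: the novel US
activates from a full inactive pool, while the trained US's pool has been
depleted by residual A2 (recency) and by retrieval priming during the test
CS exposure (association). Scores are bounded by `intensity`.

### Matched versus collapsed condition scores

`run_condition_grid()` reports all eight cells of the genotype × ITI ×
test-interval factorial, their means collapsed over test intervals, and the
*matched* scores — short-ITI training read at the short test interval,
long-ITI training at the long one. The matched contrast is the package's
primary readout and the one the sweep uses, and the choice is deliberate.

At a short test interval the trained US retains not only A2 but also
residual A1 from the just-finished trial, and this residue grows steeply as
`pd1` falls — a slow-decay model's trained US is still partly *in* A1 five
moments after training, regardless of how the training was spaced. In the
crossed-and-collapsed summary this recency carryover is averaged into the
spaced-training condition as well, where it masks the association-driven
enhancement that spaced training produces: the slow-decay model's collapsed
long-ITI score is dragged below baseline by its short-test cell even while
both of its matched contrasts move exactly as the dual-process account
predicts. Matching the test interval to the training ITI keeps the
short-term condition a test of recency and the long-term condition a test of
association, which is the dissociation the analysis is about. Both summaries
are computed and returned, so the collapsed view remains one line away.

With the default parameters the matched scores are:

```{r grid}
grid <- run_condition_grid(list(wildtype = sop_params(),
                                knockout = sop_params(pd1 = 0.11)))
grid$matched
```

The wild-type model shows strong massed and weak spaced preference; the
reduced-`pd1` model reverses the ordering and brackets baseline from the
predicted sides. The cumulative associative increment over training is
larger at `pd1 = 0.11` than at `0.2` (more A1 activity → more excitatory
learning), which the `dv` column of the trace records moment by moment.

## The reduction sweep

`pd1_reduction_sweep()` rescans the two matched conditions for `pd1 = 0.2 ·
(1 − f)` over a grid of reduction fractions `f` (default 0–70% in 0.5%
steps, matching the granularity at which such windows are conventionally
reported). A fraction qualifies when *both* strict inequalities hold
against baseline: massed score below, spaced score above. Ties do not
qualify, so `f = 0` never does. The qualifying set is checked for
contiguity and returned with its endpoints; an empty or fragmented set
triggers a warning rather than an error, since both are legitimate sweep
outcomes under other parameterisations.

Under the defaults the window opens at the first grid point (0.5%) and is
still open at the 70% range end; extending the grid shows it closing near a
96% reduction, where the massed condition's collapse of self-generated
priming is finally outweighed in the spaced condition too. The qualifying
set comfortably contains the knockout value `f = 0.45`. The window
endpoints are therefore sensitive to implementation details of the scoring
and schedule — a caveat worth keeping in mind when comparing endpoint
values across implementations of this model family, which often leave such
details (sub-step order, priming-rate form, readout moment) unstated.
Halving the grid step moves an endpoint by at most one coarse step (tested).

## The CS-duration prediction

A second qualitative prediction of the dynamics: in a single conditioning
trial, net associative strength is non-monotone in CS duration. The CS's A1
activity waxes over the first several moments and then wanes as its own
elements drain into A2, so a US arriving at intermediate delays meets more
predictor A1 than a US arriving late. `cs_duration_experiment()` defaults
to a punctate one-moment US co-terminating with the CS, which makes the
effect transparent — the acquired strength simply traces the CS's A1
trajectory. (With a long US the learning window integrates over several
moments of the A1 curve and the rising flank is no longer resolvable at
these parameter values; the intermediate-beats-long ordering survives
either way.) A duration with no CS-alone moments before US onset is
rejected as a degenerate trial.

## The synthetic behavioural stage

`map_to_exploration()` converts test-moment states to expected arm
exploration times: `time = time_scale · (w1 · pA1 + w2 · pA2)`. Defaults
are `w1 = 1`, `w2 = 0.1`, `time_scale = 200` s per unit response, giving
novel-arm times around 40 s — realistic for a two-minute test. The A2
weight needs care: the habituated arm carries a large A2 pool (~0.6 of its
elements after massed training) against an A1 signal an order of magnitude
smaller, so any `w2` above ≈ 0.15 makes the *familiar* arm the more
explored one and pushes the discrimination ratio below chance. `w2 = 0.1`
keeps A2 elements weakly response-able without letting the pool size
dominate; `habituation_series()` uses a pure-A1 readout (`w2 = 0`) for the
unconditioned-response habituation curves, where the declining quantity of
interest is A1 itself.

`generate_cohort()` draws per-animal novel/familiar/start times from gamma
distributions with the model-mapped means and a common coefficient of
variation (default `noise = 0.3`, typical of exploration-time variability;
default `n_per_group = 12`, a realistic mouse cohort). Gamma noise keeps
times positive with controllable dispersion. The generator emulates the
assay's time-in-arms readout only: it does not model arm-entry counts,
within-test time courses, inter-animal parameter variability, or any
correlation between an animal's three arm times (draws are independent).
Passing tests on these cohorts therefore demonstrates the pipeline's
statistical machinery and the model-level orderings, not fidelity to any
real animal's noise structure.

`analyze_cohort()` summarises each group's discrimination ratio
`Novel / (Novel + Familiar)` (chance 0.5, start arm excluded by the assay's
convention) with a bootstrap percentile interval and a one-sided sign-flip
test against 0.5 — exact enumeration of all `2^n` sign assignments up to
`n = 14`, Monte Carlo beyond — plus a genotype × training-ITI interaction
test that permutes genotype labels within ITI strata. Sign-flip rather than
a t test because it is exact at small n and assumption-free about the
ratio's distribution. Groups of one animal are flagged and given `NA`
intervals.

`recover_pd1()` inverts the pipeline: grid search over candidate `pd1`
values minimising the squared distance between the cohort's mean ratios per
condition and the noise-free model-mapped ratios. A noise-free cohort
recovers the generating value exactly when it lies on the grid; at 50
animals per group and `noise = 0.3` recovery lands within ±0.01–0.02 of
`pd1 = 0.11` across seeds. The objective is shallow — the ratio compresses
state differences — so much smaller cohorts identify `pd1` only coarsely.

## Determinism and seeds

All model dynamics are deterministic; identical inputs give bit-identical
outputs. Stochastic stages (cohort generation, bootstrap, permutations)
take explicit integer seeds, expanded per component by `derive_seed()` so
that adding a pipeline stage never perturbs another stage's draws, and they
restore the caller's RNG state. Result tables are written with fixed column
order and a JSON manifest embedding the configuration hash and seed.

## Problem sizes

The shipped tests run the full 0.5%-resolution sweep (141 grid points × 2
conditions), a 100,000-element Monte-Carlo oracle over 30 moments, and a
50-per-group recovery cohort — together under a minute of CPU, sizes chosen
so the whole analysis re-runs comfortably on a laptop while leaving the
statistical checks well-powered.

## Known limitations

* No extinction or decrement rule for associative strength; the model is
  for acquisition-side phenomena only.
* Stimulus presence is binary; graded salience enters only through the
  intensity parameter.
* The sweep endpoints, unlike the qualitative dissociation, depend on
  unstated-by-convention implementation details (readout moment, priming
  form, summary choice) and should be compared across implementations with
  that in mind.
* The behavioural stage models one readout (time in arms); entry counts
  are a possible extension.
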