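# sopdual

Wagner's sometimes-opponent-process (SOP) theory holds that every stimulus is
represented by a pool of memory elements, each of which is, at any discrete
"moment", inactive (I), in a primary activity state (A1) or in a secondary
activity state (A2). Presentation recruits inactive elements into A1 with
probability `p1` (the stimulus intensity); A1 elements decay into A2 at rate
`pd1` (*self-generated priming*); A2 elements return to I at rate `pd2`; and
elements in A2 cannot re-enter A1. Elements of an *associated* stimulus are
driven directly from I into A2 at a rate proportional to the predictor's A1
activity times the net associative strength `V = V⁺ − V⁻`
(*retrieval-generated priming*), where per moment

    ΔV⁺ = L⁺ · pA1(CS) · pA1(US)        ΔV⁻ = L⁻ · pA1(CS) · pA2(US)

Because only A1 elements generate vigorous responding, both kinds of priming
produce habituation: self-generated priming is recency-driven (short-term
habituation), retrieval-generated priming is association-driven (long-term
habituation), and the two compete — elements parked in A2 by one mechanism
are unavailable to the other.

`sopdual` is a deterministic discrete-moment simulator of these dynamics,
built to analyse a specific dissociation: reducing `pd1` (the modelled effect
of deleting the GluA1 AMPA-receptor subunit) *impairs* short-term habituation
— less A2 accumulates, so a recently exposed stimulus stays surprising — but
*enhances* long-term habituation, because the extra A1 activity supports more
excitatory associative learning. In a Y-maze spatial-novelty-preference assay
(exposure training to a Start and a Sample arm, then a choice including a
Novel arm) the model therefore predicts weaker novelty preference after
massed (short-ITI) training and stronger preference after spaced (long-ITI)
training, relative to baseline `pd1 = 0.2`.

The package provides:

* **Core dynamics** (`run_schedule()`, `advance_moment()`, `step_*()`):
  element-state recurrences, priming and opponent learning over arbitrary
  multi-stimulus schedules, with tidy state and link traces.
* **Paradigms** (`build_novelty_schedule()`, `run_condition_grid()`,
  `pd1_reduction_sweep()`, `cs_duration_experiment()`,
  `habituation_series()`): the novelty-preference factorial, the sweep over
  `pd1` reductions, a CS-duration conditioning prediction, and repeated
  presentation habituation curves.
* **Synthetic behaviour** (`generate_cohort()`, `analyze_cohort()`,
  `recover_pd1()`): mapping of model states to per-animal arm exploration
  times, gamma-noise cohorts, bootstrap / sign-flip / permutation inference
  on the discrimination ratio `Novel / (Novel + Familiar)`, and
  grid-search recovery of `pd1` from cohort data.
* **Configuration and I/O** (`load_config()`, `write_results()`): validated
  YAML run configurations and deterministic CSV/JSON output with a
  reproducibility manifest.

## Worked example

```r
library(sopdual)

grid <- run_condition_grid(list(wildtype = sop_params(),
                                knockout = sop_params(pd1 = 0.11)))
grid$matched
#>   genotype training_iti      score
#> 1 wildtype            5 0.09169611
#> 2 knockout            5 0.05096136
#> 3 wildtype          100 0.02609602
#> 4 knockout          100 0.05492326
```

The score is the difference in A1 activity between the novel and the trained
US at the test moment; positive values mean novelty preference. The wild-type
model prefers novelty strongly after massed training (0.092) and weakly after
spaced training (0.026); slowing the A1→A2 decay to `pd1 = 0.11` reverses
the ordering (0.051 vs 0.055), sitting below baseline in the massed condition
and above it in the spaced condition — impaired short-term but enhanced
long-term habituation from a single parameter change.

The same dissociation expressed behaviourally, with 12 simulated animals per
group and gamma exploration-time noise:

```r
cohort <- generate_cohort(list(wildtype = sop_params(),
                               knockout = sop_params(pd1 = 0.11)),
                          cohort_spec(n_per_group = 12, noise = 0.3, seed = 1))
analyze_cohort(cohort, n_resamples = 1000, seed = 1)
#>  genotype training_iti test_interval  n mean_dr ci_lower ci_upper p_vs_chance
#>  knockout            5             5 12  0.5021   0.4218   0.5695     0.47729
#>  wildtype            5             5 12  0.5918   0.5043   0.6605     0.02124
#>  knockout          100           100 12  0.5615   0.5012   0.6344     0.04883
#>  wildtype          100           100 12  0.5161   0.4581   0.5730     0.29712
#>  ...
```

Wild-type animals discriminate above chance only after massed training
(mean ratio 0.59, sign-flip p = 0.021); knockouts only after spaced training
(0.56, p = 0.049). The decay parameter is recoverable from such cohorts:

```r
recover_pd1(generate_cohort(list(ko = sop_params(pd1 = 0.11)),
                            cohort_spec(50, 0.3, 1)))
#> pd1 recovery: estimate = 0.11 (grid of 51 candidates)
```

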