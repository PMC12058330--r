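# dyadrisk

Computational analysis of social-context effects on risky decision making
in adolescent friend dyads.

Pairs of age-matched friends (ages ~12–23) repeatedly choose between a
certain $5 and risky lotteries (win probabilities {.10, .25, .50, .75, .90}
crossed with amounts {$5…$100}; 35 trials per condition). The same choice
set is replayed under different social framings: outcomes for oneself only
(*Baseline*), identical outcomes for both friends (*Identical*), or
*Opposite* outcomes — the participant keeps one option and the friend
receives the other — each with and without the friend observing. dyadrisk
is for researchers who want to fit the choice models behind this design,
apply its identifiability-based exclusion rules, and ask how the fitted
preferences change with age, on their own data or on fully synthetic
cohorts.

## The models

Risk preference is the exponent of a power utility with a logistic choice
rule:

* **Original (expected-utility) model** — `EU = p·v^α`, and
  `P(risky) = 1 / (1 + exp(β·(EU_safe − EU_risky)))`, with risk preference
  `α` (α < 1 risk averse, α = 1 risk neutral, α > 1 risk seeking) and
  inverse decision noise `β`.
* **Revised (social-weighted) model**, for the Opposite context —
  `EU = (1−w)·p_self·v_self^α + w·p_friend·v_friend^α_friend`, where
  `w ∈ [0,1]` weighs the friend's outcome and `α_friend` is a fixed
  per-participant constant estimated from the participant's predictions of
  their friend's baseline choices.

Models are fit per participant × condition by bounded multi-start maximum
likelihood. Exclusions follow the choice set's analytic identifiability:
the maximum indifference exponent of the design grid is
`ln(10)/ln(2) ≈ 3.32` (the bound for Baseline/Identical fits), exponents
above 2 change at most one noise-free choice (the stricter Opposite bound),
and fits no better than a zero-parameter chance decision maker are flagged
by AIC. Age trends are inferred with penalized-spline GAMs (mgcv) with
dyad-nested random intercepts: first derivatives and condition differences
are evaluated at 100 ages with simultaneous 95% confidence bands, and
maximal age runs where a band excludes zero are reported as significant
windows.

## Worked example

Simulate a small synthetic cohort, run the full pipeline, and look at the
friend-weight age trend:

```r
library(dyadrisk)

cfg <- pipeline_config(cohort = cohort_config(n_dyads = 24),
                       seed = 7, n_draws = 2000, verbose = FALSE)
bundle <- run_pipeline(cfg)

# per-participant fits and exclusion flags
dplyr::count(bundle$flags, excluded)
#> # A tibble: 2 × 2
#>   excluded     n
#>   <lgl>    <int>
#> 1 FALSE      277
#> 2 TRUE        59

# mean fitted risk exponent by condition (after exclusions)
fits <- dplyr::inner_join(bundle$fits,
                          dplyr::filter(bundle$flags, !excluded),
                          by = c("participant_id", "condition"))
round(tapply(fits$alpha, fits$condition, mean), 2)
#>            Baseline           Identical   ObservedIdentical    ObservedOpposite
#>                0.60                0.61                1.09                0.50
#>            Opposite UnobservedIdentical  UnobservedOpposite
#>                0.53                0.97                0.56

# age trend of the friend-outcome weight in the Opposite condition
bundle$analyses$friend_weight$windows
#> # A tibble: 0 × 4
#> # ℹ 4 variables: from_age <dbl>, to_age <dbl>, direction <chr>, n_points <int>
```

Read: baseline exponents average 0.60 (risk averse, near the generator's
0.55 target), and the observed Identical blocks sit near risk neutrality
(their generative shift). 59 of 336 participant × condition fits are
excluded, mostly Opposite-context fits whose friend weight collapsed to the
`w < 1e-6` bound — the weight is unidentifiable for participants who
believe their friend's risk preference matches their own (see the methods
vignette). At 24 dyads the simultaneous band on the friend-weight
derivative is too wide to isolate a significant age window; the
cohort-scale checks in the test suite use 64 dyads, where the injected
young-age Opposite earnings gap is detected and the fitted friend weight
declines with age.

A seeded synthetic trial table itself looks like:

```r
cohort <- generate_cohort(cohort_config(n_dyads = 2), seed = 1)
trials <- generate_study_dataset(cohort, seed = 2)
dim(trials)
#> [1] 1120   10    # 4 participants × 8 conditions × 35 trials
```

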