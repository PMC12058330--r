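---
title: "Models and methods behind dyadrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dyadrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadrisk)
```

dyadrisk implements a computational analysis of how social context shifts
risk preferences across adolescence. Pairs of age-matched friends choose
between a certain $5 and risky lotteries; the same lottery set is replayed
under different social framings (outcomes for oneself only, identical
outcomes for both friends, or *opposite* outcomes where the unchosen option
goes to the friend, each with and without the friend watching). The package
provides the choice models, per-participant maximum-likelihood fitting,
principled exclusions, behavioral measures, a parameter-recovery harness,
nonlinear age-trend inference, and a synthetic dyad-cohort generator that
stands in for participant data.

## The task and its identifiability limits

Each condition crosses win probabilities {.10, .25, .50, .75, .90} with
amounts {$5, $10, $20, $30, $40, $50, $100} against a certain $5 — 35
trials, order randomized, screen side counterbalanced (17/18, since 35 is
odd; the extra side is decided by the seed).

Risk preference is the exponent $\alpha$ of a power utility,
$EU = p\,v^\alpha$: $\alpha < 1$ concave (risk averse), $\alpha = 1$
expected-value maximizing, $\alpha > 1$ convex (risk seeking). For a risky
option $(p, v)$ against the certain $s$, the two utilities cross at the
*indifference exponent* $\alpha^* = \ln(1/p)/\ln(v/s)$. The largest finite
$\alpha^*$ over the set — `max_recoverable_alpha()`, which is
$\ln 10 / \ln 2 \approx 3.32$ for this grid — bounds what choices can
reveal: above it every noise-free choice vector is identical. Between 2 and
3.32 only a single trial's choice changes, which motivates the stricter
bound of 2 used for the Opposite context, where a third parameter must also
be identified. These closed forms are the declared meaning of
"recoverable" throughout the package.

Money is handled as plain double-precision dollars. On this grid every
expected value is a sum of terms exact to well below a tenth of a cent, so
integer-cent arithmetic would add interface friction with no numerical
benefit; earnings are asserted and reported at cent precision.

## Choice models

Choices follow a logistic rule with inverse decision noise $\beta$:
$P(\text{risky}) = 1/(1 + \exp(\beta\,(EU_{safe} - EU_{risky})))$. Larger
$\beta$ yokes choices more tightly to expected utility; $\beta = 0$ is a
coin flip. Log-probabilities are evaluated on the log scale via `plogis()`
directly, so likelihoods remain finite even when $\beta\,\Delta EU$ reaches
the thousands (possible with $100 amounts and $\alpha$ near 2).

Utilities are computed on raw dollar amounts; the $\beta$ scale absorbs
units. One consequence worth knowing: the *probability* of a risky choice
is then not monotone in $\alpha$ on every trial (on the dominated $5-vs-$5
trials the utility difference $p\,5^\alpha - 5^\alpha$ grows more negative
as $\alpha$ grows). Noise-free choices are monotone — risky exactly when
$\alpha$ exceeds the trial's indifference exponent — and the tests assert
monotonicity at that level.

In the Opposite context the participant keeps one option and the friend
receives the other. The revised model values an assignment as
$(1-w)\,p_{self}\,v_{self}^{\alpha} + w\,p_{friend}\,v_{friend}^{\alpha_{friend}}$:
$w \in [0, 1]$ is the friend-outcome weight, and $\alpha_{friend}$ is a
per-participant constant — the exponent recovered from the participant's
trial-by-trial predictions of their friend's baseline choices — never re-fit
jointly. "Chose risky" means the risky option was assigned to *oneself*,
with the friend implicitly receiving the safe option, and vice versa. A
gains-only prospect-theory variant (one-parameter Tversky–Kahneman
probability weighting; no loss aversion because the task has no losses) is
included purely as a comparison candidate for the AIC harness; its exact
form is this package's choice.

## Fitting and exclusions

Each participant × condition block is fit individually (not hierarchically,
to keep age assumptions out of the estimation stage) by maximizing the
likelihood over a bounded box — $\alpha \in [0.01, 5]$,
$\beta \in [0.001, 50]$, $w \in [0, 1]$ — from a multi-start grid
($\alpha \in \{0.2, 0.55, 1.0, 1.8\}$, $\beta \in \{0.5, 2, 8\}$,
$w \in \{0.1, 0.35, 0.7\}$) refined by L-BFGS-B. The likelihood is
multimodal in $(\alpha, \beta)$ at low $\beta$, hence the grid. Estimates
on a box boundary are reported as-is with a `boundary` flag, never clipped.
`n_starts_agreeing` counts starts whose optimum lies within 0.01
log-likelihood of the best; on data with $\beta \ge 2$ nearly all starts
agree.

Exclusions mirror the identifiability analysis: $\hat\alpha > 3.32$ in
Baseline/Identical contexts; $\hat\alpha > 2$ or $\hat w < 10^{-6}$ in
Opposite contexts; and fits whose AIC is at or beyond that of a chance
decision maker. The chance comparator deserves a note: a pure coin-flip
model has *no* free parameters, so `apply_exclusions()` compares against
$-2n\ln(0.5)$ (i.e. `chance_aic(n, k = 0)`). Comparing at the fitted
model's own $k$ would make the rule vacuous — chance is nested in every
fitted model at $\beta = 0$, so the fitted AIC can never exceed a same-$k$
chance AIC except by optimizer round-off. With the zero-parameter
comparator, a fit survives only if its likelihood beats chance by more than
its own penalty. Exclusions are applied per condition, not participant-wide;
a config toggle disables them for full-sample sensitivity analyses.

## Behavioral measures

`proportion_risky()` is the count ratio of risky choices. Simulated
earnings are the sum of the *expected values* of the chosen options (no
lottery outcomes are sampled — the measure is defined on EVs), reported as
a proportion of the EV-maximizing ceiling, which is $662.50 for this grid.

## The synthetic cohort

The generator emulates the study's design so every downstream stage can be
exercised without any participant data. Defaults, fixed once:

* 64 dyads (128 participants), ages uniform on 12.0–22.8 years, pairs
  matched within 1.39 years (truncated-normal gap, mean 0.46);
* baseline exponents $\alpha \sim N(0.55, 0.23)$ truncated to (0.05, 2);
* inverse noise $\beta \sim \mathrm{LogNormal}(\ln 3, 0.5)$ — a median of 3
  puts simulated agents in the moderately reliable regime where multi-start
  fits agree and chance-AIC exclusions are rare;
* friend weight $w = \mathrm{clamp}(0.67 - 0.019\,\mathrm{age} + N(0, 0.1), 0, 1)$,
  i.e. a linear decline from about 0.45 at age 12 to 0.24 at 22.8 with a
  cohort mean near 0.34;
* an additive Opposite-context exponent shift of $+0.14$ at age 12 tapering
  linearly to zero by age 15.1 — an early-adolescent window of extra risk
  acceptance injected additively rather than claiming any particular
  functional form;
* beliefs about the friend's exponent equal to the partner's true exponent
  plus $N(0, 0.1)$ noise — imperfect but informative;
* Identical-context shifts (+0.04 solo; +0.39 unobserved, +0.49 observed in
  the dyad session) matching the corresponding condition means; observation
  deliberately has *no* effect on $w$.

What the generator does **not** emulate: real choice data are not
guaranteed to follow the logistic EU family, trial-order and session
effects are absent, ages are uniform rather than two recruited bands, and
the true generative age structure of the study population is unknown — the
generator is calibrated to summary statistics only. Passing tests therefore
demonstrate that the pipeline recovers structure *of the kind assumed*, not
that the study's exact window endpoints would be reproduced on real data.

## Parameter recovery and its limits

`run_parameter_recovery()` draws agents ($\alpha \sim U(0,2)$,
$w \sim U(0.05, 0.95)$, $\beta \sim \mathrm{LogNormal}(\ln 3, 0.5)$,
friend exponents from the same truncated normal as the cohort), simulates
one 35-trial block each, refits, and reports correlation, bias and RMSE.
With 200 agents the revised model's true-vs-fitted correlations sit near
0.7 for $\alpha$ and 0.65–0.73 for $w$ across seeds.

The weight's ceiling has a structural cause: the two utility-difference
vectors $u(\alpha)$ and $u(\alpha_{friend})$ over the 35-trial grid are
highly correlated, and when the two exponents nearly coincide the model
collapses to a one-dimensional ridge on which $w$ trades off against
$\beta$ — $w$ is then essentially unidentified, estimates pile up at the
$w = 0$ end of the ridge (the $w \to 1$ end is truncated by the $\beta$
bound), and $\hat w$ acquires a downward bias that is visible even at true
$w = 0.5$. Point checks of $w$ recovery in the tests therefore use friend
exponents well separated from the self exponent; the aggregate correlations
above include the degenerate draws, as any realistic cohort would.

## Age-trend inference

`fit_age_smooth()` fits, with mgcv,
`dv ~ condition + s(age, by = condition, bs = "cr", k = 10)` plus random
intercepts for dyad and participant-within-dyad, smoothing parameters by
REML. Cubic regression splines with basis dimension 10 are the standard
defaults of this GAM methodology. In automatic mode the participant
intercept is dropped when no participant contributes more than one row (it
would be confounded with the residual), and the finest random term is
dropped while the coefficient count approaches the sample size — a model
within ten coefficients of saturation estimates nothing useful about
either variance component and destabilizes the Beta-family fitter. An
explicit `random` argument overrides both rules. Proportions (earnings shares) use a Beta
likelihood with logit link; values at the boundary are first squeezed by
$(y(n-1)+0.5)/n$, the standard transform, and flagged in the result.

Age inference never reads p-values off the smooth directly. The first
derivative of the fitted curve is evaluated by central finite differences
(step $10^{-4}$ of the age range — stable for cubic splines) at 100 ages
spanning the observed range, with a *simultaneous* 95% band: coefficient
vectors are drawn from the approximate Gaussian posterior (10,000 draws by
default, seeded), the 95th percentile of the maximum absolute standardized
deviation across the 100 points becomes the critical multiplier, and
pointwise intervals are widened by it. Maximal runs of points whose band
excludes zero are reported as significant age windows. Condition contrasts
use the same machinery on the difference of fitted curves (smooths plus
parametric offsets, random intercepts excluded). For Beta-family fits the
bands live on the logit scale.

Tie-breaks and degenerate inputs: a difference of a condition against
itself is exactly zero with a zero-width critical multiplier; singular
coefficient covariances raise an error rather than producing a band; fewer
distinct ages than basis functions raises an error suggesting a smaller
`k`.

The pipeline answers the four study questions in order — baseline age
trend; Identical- and Opposite-vs-Baseline difference smooths (the two
social contexts are never contrasted directly, as they differ in cognitive
demand); observation contrasts within each context via a 4-level condition
factor rather than a 2×2 interaction; and the age trend of $\hat w$ — and
no participant excluded for a condition enters that condition's analysis.

## Problem sizes and numerical choices in the test-suite

The tests exercise the pipeline at sizes chosen to make their statistics
stable: recovery checks average 10 seeded runs of 200 agents; the
end-to-end cohort checks use the default 64 dyads; the null calibration of
the derivative windows uses 200 simulated cohorts with 2,000 posterior
draws per band (the acceptance of a ~5% family-wise rate needs only that
resolution); the parametric-bootstrap cross-check of the band construction
uses a 40-observation fixture with 500 refits. The pipeline smoke tests run
10 dyads with a basis dimension of 5.

## Known limitations

* No loss domain and no ambiguity: the task only ever offers gains with
  stated probabilities.
* The friend weight is intrinsically hard to identify when a participant
  believes their friend's risk preference matches their own; reported
  $\hat w$ for such participants should be read with the bias above in
  mind.
* The prospect-theory candidate is a stand-in with one weighting parameter;
  conclusions about prospect theory generally should not rest on it.
* Window endpoints from difference smooths are implementation- and
  sample-sensitive; on synthetic cohorts they are checked qualitatively
  (detection confined to the injected young-age window), not for exact
  endpoints.
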