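---
title: "Dynamic prediction by landmarking for recurrent asthma attacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic prediction by landmarking for recurrent asthma attacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidemark)
```

## The setting and the data model

The package targets two-arm prevention trials in which each subject can
experience the event many times: young children at high risk of asthma,
randomized to medication or placebo at entry and followed for 18 months
(540 days), with every attack recorded. The data model is the standard
counting-process layout: one row per *episode*, the half-open interval
`(start, stop]` during which the child was awaiting their next attack,
with `status = 1` if the attack occurred at `stop`. Two variables are
derived on input and used everywhere downstream: the *gap time*
`stop - start` (the renewal timescale) and the *event order*, the 1-based
sequence number of the awaited attack. `read_cohort()` validates the
invariants (positive episode lengths, binary status and arm, episodes of
a child non-overlapping and ascending, arm constant within child) and
rejects rows with missing modelling values rather than imputing them.
Censored episodes that are not a child's last are accepted with a warning
(`strict = TRUE` rejects them), since a follow-up gap is a data oddity the
analyst should see but not necessarily a fatal one.

## Why landmarking

A Cox model fitted once at baseline cannot issue a prediction *conditional
on being attack-free at day s*, and when the treatment effect varies over
follow-up its single coefficient is a hard-to-interpret average. The
landmark idea is to re-fit a simple model at each prediction time on
exactly the information a clinician would have then:

1. keep the subjects at risk at the landmark time `s` (left truncation);
2. administratively censor at the horizon `s + w` (only the next `w` days
   matter for the decision at `s`);
3. freeze the covariates at `s` — here the arm and `cnts`, the order of
   the awaited attack, which summarises the attack history;
4. fit a Cox model to this *sliding landmark dataset*.

`make_sliding_dataset()` implements the construction; the window outcome
is the time to the *first* attack after `s` (classic landmarking). An
`"all_episodes"` mode that keeps every episode inside the window (an
Andersen-Gill analysis with covariates still frozen at `s`) is available
behind a flag for sensitivity analyses.

Boundary conventions, chosen once and tested: a subject is at risk at `s`
iff an episode satisfies `start <= s < stop`, so an attack at exactly `s`
puts the child in the risk set of the *next* attack; an attack at exactly
the horizon `s + w` counts as an event; reaching the horizon attack-free
is administrative censoring (`status = 0`).

### Timescale

The landmark grid runs on **calendar time since study entry**. The
supporting single-fit models are offered on both timescales (calendar and
gap) because they answer different questions, but a landmark grid spanning
0–400 days combined with an attack-history covariate is only coherent on
the calendar scale: a child's position on the gap scale resets at every
attack, while the landmark clock must not. A `timescale`-like choice
therefore does not exist for the landmark machinery itself; the gap scale
enters through the per-order Kaplan-Meier curves and the gap-time Cox and
frailty models.

## The supermodels

Per-landmark fits ignore that neighbouring landmark datasets overlap
heavily and that `beta_LM(s)` should vary smoothly. Stacking all landmark
datasets into the *super prediction dataset* (`make_super_dataset()`)
gives a pseudo partial likelihood — the sum of the per-landmark partial
log-likelihoods, optionally weighted by non-negative landmark weights
`psi(s)`. Two fits are provided:

* `fit_supermodel_stratified()` (**supermodel 1**): one baseline hazard
  stratum per landmark, common `treatment` and `cnts` coefficients.
* `fit_supermodel_unstratified()` (**supermodel 2**): a single baseline
  with the landmark basis `LM1 = s/150`, `LM2 = (s/150)^2` as main
  effects. With `treatment_interactions = TRUE` the treatment effect
  itself is expanded on the basis,
  `beta(s) = theta1 + theta2*LM1 + theta3*LM2`, and `beta_lm()` evaluates
  it; the default keeps the four-column model (treatment, cnts, LM1, LM2)
  because that is the reporting layout the analysis is built around.

Because one child contributes rows to many strata, model-based standard
errors are fictions; both supermodels always carry a sandwich covariance
clustered on the child, and the reported `z`/`p` use it.

Two exactness properties anchor the construction and are asserted in the
test suite: with uniform weights the stacked stratified fit *with
per-stratum interaction terms* reproduces every independent per-landmark
fit to numerical precision (the pseudo likelihood separates); and strata
given zero weight drop out exactly, leaving the fit on the reduced grid.

### Predictions

`breslow_baseline()` computes, per stratum, the baseline hazard increment
at each event time — events at `t` divided by the risk-set sum of
`exp(X beta)` — and `predict_dynamic()` turns it into the conditional
event-free probability
`exp(-sum_{s < t <= s+w} h0(t|s) exp(X beta_LM(s)))`. The Breslow form is
used for the baseline regardless of the tie correction used for the
coefficients; with the default Efron fit on tied data the two are
inconsistent at fourth-decimal order, which is far below the Monte Carlo
noise of any quantity built from a 232-child cohort.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| grid `from/to/by` | 0–400 by 5 days | 81 landmark prediction times |
| `window` | 120 days | horizon of each prediction |
| basis `scale` | 150 days | `LM1 = s/150`, `LM2 = (s/150)^2` |
| `ties` | `"efron"` | tie correction for coefficients (`"breslow"` available; the baseline is always Breslow) |
| `cnts` | `"order"` | awaited-attack order; `"previous"` uses order − 1 |
| `cnts_cap` | 20 | caps the history covariate; the emulated trial's tail reaches 38 attacks, and a handful of such rows would otherwise dominate the `cnts` column at late landmarks |
| `psi(s)` | 1 on the grid | landmark weights in the pseudo likelihood |

The grid, window and basis scale defaults are the analysis settings the
package is designed to reproduce; they are data-analysis choices, not
estimates, and `pipeline_config()` exposes all of them.

## The supporting model suite

`model_comparison()` fits the five standard descriptions of the treatment
effect: Andersen-Gill Cox on calendar time (all episodes, common
baseline), Cox on the first attack only, Cox on gap time, and shared
gamma-frailty versions of the calendar and gap models. The frailty model
gives child `i` a multiplicative random effect `Z_i ~ Gamma(mean 1,
variance theta)`; within-child correlation of attacks is absorbed by
`theta` rather than biasing the arm contrast's precision.

`fit_gamma_frailty()` estimates it by EM: the E-step replaces `Z_i` by its
gamma posterior mean `(1/theta + D_i) / (1/theta + Lambda_i)` (events
over accumulated model hazard), the M-step refits the Cox model with
log-frailty offsets, and `theta` is maximized on the profile marginal
log-likelihood by bounded 1-D search on `[0, 5]` (tolerance `1e-4`; inner
EM tolerance `1e-6`, at most 200 iterations; `theta = 0` reduces exactly
to the plain Cox fit, and the marginal likelihood is asserted
non-decreasing along the EM trace). The reported standard error of `beta`
is a profile-likelihood SE — the numeric Hessian of the marginal
log-likelihood in `beta` at `theta`-hat with baseline and frailties
profiled out — which is wider than the naive offset-model SE because it
propagates the heterogeneity. The estimator agrees with
`survival::coxph(... + frailty(id, "gamma"))` to well under `0.001` on
simulated cohorts, and that agreement is a standing cross-check in the
tests, not the implementation.

Kaplan-Meier curves (`km_by_event_order()`) are drawn on the gap
timescale per attack order: the order-`k` risk set is every child who has
an order-`k` episode (experienced `k−1` attacks and was followed for the
`k`-th), with the episode's gap as time. `km_all_episodes()` reproduces
the deliberately naive all-episodes curve — every episode treated as an
independent individual — and flags its output with a `naive` attribute so
reports can label it as descriptive only.

## The synthetic cohort generator

`simulate_cohort()` generates the study conditions the analysis assumes:
232 children in arms of 113 (medication) and 119 (placebo), 540 days of
administrative follow-up, conditional attack intensity
`Z_i * lambda0 * exp(beta * trt_i)` with `beta = -0.3` and gamma frailty
of variance 0.5, and `lambda0 = 3.53/540` per day so that the placebo-arm
mean attack count matches the emulated trial's 3.53 attacks per child
(the treated arm is proportionally lower, putting the expected overall
mean near 3.1). Event times come from exact inversion of the cumulative
intensity — unit-exponential increments on the transformed timescale, no
thinning — for either a calendar-time Poisson process or a renewal (gap)
process, with piecewise-constant `lambda0` supported. Each child has its
own random substream derived by hashing the cohort seed with the child
index (with a short burn-in; nearby raw seeds give correlated leading
draws, which a blocked arm allocation would otherwise convert into a
spurious treatment effect — this was caught by the parameter-recovery
tests and is exactly the class of defect they exist for).

What the generator deliberately does **not** emulate: dropout or any
informative censoring (everyone reaches day 540), covariates beyond the
arm, seasonal or age-driven hazard shapes, and the extreme right tail of
the real attack distribution (a constant-rate gamma-frailty process makes
counts above ~30 astronomically rare, while the real trial recorded up to
38). Green tests on synthetic cohorts therefore demonstrate correctness
of the machinery under the stated model, not robustness of the scientific
conclusions to dropout or model misspecification.

Verification sizes used by the test suite, chosen to keep Monte Carlo
error well inside each assertion's margin: calibration of the mean attack
burden at 20 000 children (MC error ~0.02 attacks); parameter recovery at
1 000 children × 50 seeds (Andersen-Gill coverage of the true `beta`, and
mean frailty-EM estimates of `(beta, theta)` within two Monte Carlo
standard errors of the truth); exactness oracles (stacked-fit
separability, brute-force Breslow and product-integral enumerations) at a
few hundred rows where `O(n^2)` reference loops are instant.

## Numerical choices and degenerate inputs

* Cox fits start at `beta = 0` with tight convergence
  (`coxph.control(eps = 1e-11, iter.max = 100)`) so that the exactness
  oracles hold at `1e-6` and better.
* A covariate that is constant in a landmark dataset (e.g. `cnts` at
  `s = 0`, where every child awaits attack 1) is dropped with an `NA`
  coefficient and a flag — a skipped coefficient, not a crashed pipeline.
  Landmark points with no event in the window are recorded as skipped
  with a reason by `landmark_coefficient_path()`.
* An empty risk set at a requested landmark yields an empty dataset
  signal, not an exception; `fit_supermodel_*` drop event-free strata
  with a log message.
* A single-landmark grid makes `LM1`/`LM2` constant; supermodel 2 refuses
  it by name, supermodel 1 reduces exactly to the simple landmark fit.
* Ties: events precede censorings at equal times; `exp(coef)` tables are
  computed from raw-scale coefficients (no internal centering), so
  printed values are directly comparable across implementations.
* The frailty variance search hitting its upper bound (5) warns rather
  than fails; a boundary solution at 0 returns the plain Cox fit.

## Limitations

Landmarking is an approximation by construction: each landmark model is a
working model for a window, and the stacked pseudo likelihood is not a
true likelihood (hence the clustered sandwich everywhere). The package
fits no spline basis beyond the quadratic, no competing risks, no joint
longitudinal-survival model, and no penalized variants; the frailty
distribution is gamma only. These are scope decisions: the quadratic
basis and the four-column supermodel are the reporting layout this
analysis standardizes on, and anything richer belongs to a different
toolchain.
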