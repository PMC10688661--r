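# slidemark

Dynamic prediction of event-free probabilities in recurrent-event trials by
**landmarking**, built for the setting of a two-arm asthma-prevention trial
in young children: each child may suffer many asthma attacks over an
18-month follow-up, and the clinical question at any day *s* of follow-up
is *"given that this child is attack-free right now, what is the chance of
staying attack-free for the next w days — and is the medication still
helping?"*

A single Cox model cannot answer that: it conditions on baseline only, and
a time-varying treatment effect makes its one coefficient an average over
follow-up. Landmarking answers it directly.

## The method

For a landmark time `s` and prediction window `w`, the **sliding landmark
dataset** keeps the subjects still at risk at `s` (left truncation),
administratively censors everything after the horizon `s + w`, and freezes
the covariates at `s` — here the treatment arm and `cnts`, the sequence
number of the attack the child is awaiting. The **simple landmark model**
is a Cox model on that dataset,

    h(t | X, s) = h0(t | s) exp(X * beta_LM(s)),    s <= t <= s + w,

fitted at every point of a grid of landmark times (default 0, 5, …, 400
days; window 120 days; 81 datasets). Stacking the 81 datasets gives the
**super prediction dataset**, on which two supermodels are fitted:

* **supermodel 1** — stratified on `s` (one baseline hazard per landmark),
  common coefficients, sandwich covariance clustered on the child (the
  same child appears in many overlapping landmark datasets);
* **supermodel 2** — unstratified, with landmark basis terms
  `LM1 = s/150`, `LM2 = (s/150)^2` entering the linear predictor.

The landmark-specific baseline hazard uses Breslow increments

    h0_hat(t | s) = d(t) / sum_{j at risk at t} exp(X_j * beta_hat),

and the dynamic conditional event-free probability reported to the
clinician is

    P(attack-free through s + w | at risk at s, X)
      = exp( - sum_{s < t <= s+w} h0_hat(t | s) * exp(X * beta_LM(s)) ).

Around this core the package provides the standard recurrent-event model
suite used to describe such a trial — Andersen-Gill Cox on calendar time,
Cox on gap time, Cox on time to first attack, shared gamma-frailty
variants fitted by an EM profile-likelihood algorithm, and Kaplan-Meier
curves by attack order — plus a calibrated synthetic cohort generator so
the whole analysis is runnable and testable without the trial export.

## Worked example

```r
library(slidemark)

co <- simulate_cohort(default_params())
co
#> Recurrent-event cohort: 232 subjects (113 medication / 119 placebo),
#>   900 episodes, 668 attacks (mean 2.88/subject)

round(model_comparison(co), 3)
#>                        coef exp(coef) se(coef)      z     p theta
#> Cox-calendar         -0.262     0.769    0.078 -3.347 0.001    NA
#> Cox-first event      -0.118     0.888    0.142 -0.835 0.404    NA
#> Cox frailty-calendar -0.262     0.769    0.110     NA    NA 0.342
#> Cox-gap              -0.241     0.786    0.079 -3.069 0.002    NA
#> Cox frailty-gap      -0.285     0.752    0.118     NA    NA 0.441

g <- landmark_grid()          # s = 0, 5, ..., 400; window 120 days
super <- make_super_dataset(co, g)
sm1 <- fit_supermodel_stratified(super)
sm1
#> Landmark supermodel (stratified), grid of 81 landmark points, window 120 days
#>                 coef exp(coef)  se(coef) robust se      z        p
#> treatment -0.2301132 0.7944436 0.0223422 0.0957900 -2.402 1.63e-02
#> cnts       0.1902479 1.2095494 0.0070056 0.0258220  7.368 1.74e-13

bl <- breslow_baseline(sm1$fit)
predict_dynamic(sm1, bl, c(treatment = 1, cnts = 2), s = 100, w = 120)
#> [1] 0.616
```

Reading the output: on this synthetic cohort (generated with a protective
log hazard ratio of −0.3 and between-child frailty variance 0.5) every
model agrees the medication lowers the attack hazard (hazard ratios
0.75–0.89); the frailty rows show the same effect with a wider standard
error once within-child correlation is absorbed; in the supermodel each
previous attack multiplies the short-term attack hazard by about 1.21; and
a medicated child still at risk at day 100 who is awaiting their second
attack has a 61.6 % chance of staying attack-free through day 220.
`landmark_coefficient_path(co, g)` traces how both effects drift over
follow-up, and `run_pipeline()` writes every table, curve and a run
manifest to a directory in one call.

Real trial exports in the deposited counting-process layout
(`id.w, trt.w, start.w, stop.w, st.w, nn, fevent`) are read with
`read_cohort(path)`; a different layout is remapped with
`cohort_dialect()`.

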