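---
title: "Modelling perceived effort in grip force-matching: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perceived effort in grip force-matching: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(effortsens)
library(dplyr)
```

## The scientific problem

In an isometric force-matching task, a participant squeezes a hand
dynamometer so that the exerted force stays inside a narrow band around a
target level — expressed as a fraction of that hand's maximal voluntary
contraction (MVC) — holding it there for a required total time within a
fixed trial window. After each trial they rate *perceived effort* on a
0–100 visual-analogue scale. Because the band must be *matched*, not merely
exceeded, failures occur, and their frequency rises with the target force.

`effortsens` implements the full analysis chain for such experiments:

1. a **synthetic-cohort generator** reproducing the task's statistical
   structure, so every downstream stage is testable without any recorded
   data;
2. **preprocessing**, including a correction for a cross-hand MVC scaling
   error and participant-level exclusion rules;
3. **trace feature extraction** (area under the force curve, coefficient of
   variation, initial overshoot, excess force, cumulative force, lag
   features);
4. **link selection**: which transform of force best predicts ratings,
   compared by BIC across linear mixed-effects models;
5. **sensitivity estimation**: per-participant Huber robust regressions of
   rating on squared force and failure, followed by second-level
   regressions on symptom scores (PHQ9 for depressive symptoms, AES for
   apathy) under Benjamini–Hochberg FDR control;
6. a **two-step robust ridge** quantifying each participant's weighting of
   all trial features.

## The generative model

### Task design

The default `task_design()` encodes one session: five target levels
\{0.2, 0.4, 0.6, 0.8, 1.0\} of MVC, four repetitions per level and hand
except three at the maximal level, a ±5% multiplicative band, a 7-s window
with a 3-s required hold, and 250 Hz sampling — 38 trials, hands strictly
alternating. The hold criterion is **cumulative** by default: the task
wording ("a total of 3 s") admits either reading, so both are implemented
(`outcome_mode = "consecutive"`), with cumulative as the default because it
is the literal reading of "a total of".

### Force traces

`simulate_force_trace()` generates a trace as a linear ramp (0.6 s) to a
peak, an exponential settle (time constant 0.4 s) to an *intended* level,
and Ornstein–Uhlenbeck wobble (correlation time 0.25 s) whose stationary SD
is proportional to the intended level — the classic signal-dependent noise
of motor control. Two further stochastic components make the simulator
reproduce the task's phenomenology:

* an **aiming error**: the intended level is `target * (1 + e)` with
  `sd(e) = 0.022 * exp(2.5 * target)`. Force reproduction degrades steeply
  near maximal contraction; this is what makes the failure rate climb
  across the five levels (roughly 0.15 → 0.87 under defaults), matching the
  strongly force-dependent failure rates such tasks show.
* an **initial overshoot**: the ramp peaks at `intended * (1 + o)`,
  `sd(o) = 0.12`, then settles. This gives the initial-peak feature genuine
  variance.

All three components scale with a per-participant `motor_noise_scale`
(lognormal across the cohort, median 1, log-SD 0.25), which produces the
wide between-participant spread in failure proportions seen empirically.
Setting it to 0 yields a trace that ramps and holds exactly at the target —
the noise-free limit used by the exact-recovery tests.

These constants were chosen once, by matching the simulated failure-rate
curve to the qualitative shape and overall failure level reported for this
task class, and are not adjusted thereafter.

### Ratings

Ratings follow a quadratic psychophysical law with an additive failure
effect:

\[
\text{rating} = \beta_0 + \beta_F f^2 + \beta_X \cdot \text{failure} +
\varepsilon,\qquad \varepsilon \sim N(0, \sigma_r^2),
\]

clipped to [0, 100]. Per-participant parameters come from
`cohort_population()`: intercepts ~ N(10, 5), force sensitivities
\(\beta_F\) ~ N(70, 15) (so a maximal squeeze lands near the top of the
scale), failure sensitivities \(\beta_X\) ~ N(8, 6), rating noise SD 7.

### Symptom couplings

A standard-normal latent symptom severity drives everything:
PHQ9 is a discretised logistic map of the latent (only its monotone,
approximately linear association matters downstream); AES is the same kind
of map of a partially shared latent (correlation 0.4), so apathy correlates
with depression without carrying independent coupling to the
sensitivities. Sensitivities are built as
\(\mu + \sigma(c\,z + \sqrt{1-c^2}\,e)\), making the coupling `c` a
population correlation. Defaults: force coupling −0.5, failure coupling
+0.5, intercept coupling +0.3 — the sign pattern the analysis is designed
to detect. Because AES relates to the sensitivities only through the shared
latent, the second-level partial coefficient for AES is ~0 while PHQ9
carries the coupling, mirroring the dissociation the analysis reports.

### The MVC miscalibration

With `miscalibrate = TRUE` the generator emulates a cross-hand scaling
error: behaviour (trace, outcome, rating) is driven by
`nominal * MVC_opposite / MVC_own` while the log keeps the nominal
fraction. `correct_target_forces()` recovers the experienced fractions
(dominant × `mvc_nondom/mvc_dom`, nondominant × the reciprocal);
`apply_miscalibration()` is its exact inverse, useful for round-trip
checks. Preprocessing then computes MVC ratios (dominant/nondominant) and
removes the top quartile — `floor(n/4)` participants, so 108 → 81 — because
those participants' two hands saw the most mismatched targets. Ties at the
quartile boundary are broken by stable participant-id order and flagged;
the quantile convention (remove exactly `floor(n/4)`) was chosen to
reproduce the 108 → 81 count exactly.

### Outlier exclusions

On the post-quartile snapshot, participants are excluded when their
Spearman force–rating correlation or failure proportion lies outside
mean ± 2.5 SD, when the correlation is undefined (zero variance), or when
they succeeded on every trial (a constant failure predictor would make the
first-level regression rank deficient). Both outlier criteria use the same
snapshot rather than sequential re-estimation; re-running the step on the
retained cohort therefore removes no one.

## Estimation choices

* **Huber IRLS** (`fit_participant_robust()`): tuning constant 1.345 (95%
  Gaussian efficiency), MAD residual scale re-estimated each iteration, at
  most 50 iterations, tolerance 1e-8. With a very large constant the fit
  reduces to OLS, which the tests exploit as an oracle; an independent
  cross-check against `MASS::rlm` agrees to ~1e-5.
* **Link grid** (`fit_link_models()`): the hyperbolic and exponential
  transforms are fixed parameter-free forms `f/(1+f)` and `exp(f)−1`,
  keeping the mixed model linear in its coefficients. Estimation is full ML
  (not REML) so BIC is comparable across cells; ratings are rescaled to
  [0, 1] identically in every cell (BIC differences are invariant to a
  common affine response rescaling). Non-converged cells are excluded from
  selection; exact ties resolve toward the simpler random-effects
  structure, then the link order listed above.
* **Second level** (`fit_group_regression()`): both sensitivities are
  regressed on PHQ9, AES, sex (0/1), age, and MVC ratio; continuous
  variables z-scored, classical normal-theory p-values, and exactly four
  symptom coefficients (PHQ9/AES × force/failure) form the
  Benjamini–Hochberg family.
* **Two-step ridge** (`fit_cohort_ridge()`): within-participant
  standardisation (fits and betas are compared across participants), Huber
  trial weights reused in the validation MSE (they encode trial
  reliability, not fold membership; unweighted validation is available via
  `weighted_cv = FALSE`), 50 log-spaced lambdas in [1e-3, 1e3], 10 seeded
  shuffled folds, and an unpenalised intercept so the λ = 0 limit equals
  the weighted least-squares fit exactly.
* **Sensitivity analyses**: intercepts can be re-estimated after dropping
  trials rated above a cap (default 90 in the pipeline) to rule out
  ceiling-compression artefacts; `actual_force_sensitivity()` swaps the
  squared target force for the squared area under the force curve.

## Numerical and degenerate-input behaviour

Rank-deficient designs (single-class outcomes, duplicated features) raise
classed errors naming the offending columns; zero-variance ratings, empty
traces, non-positive MVCs and out-of-range p-values are rejected rather
than silently propagated. A trace whose mean force is zero yields an NA
coefficient of variation with a warning and a flag in the feature matrix;
peak detection falls back to the global maximum (flagged) on monotone
traces so every trial yields a feature row. The first trial's undefined lag
features are dropped, not imputed.

## Simulation sizes used in validation

The package's validation studies (in the test suite and
`scripts/acceptance.R`) use sizes chosen to estimate each property
stably: 20 seeded cohorts of 40 participants for link recovery, 20 cohorts
of 100 for coupling recovery, 200 replicates of 60 for the null
false-positive rate, 200 trials per force level for the failure curve, and
a 108-participant cohort for the exclusion counts. Traces are simulated at
25–50 Hz there: outcome probabilities are insensitive to the sampling rate
(the band-hold criterion is a time fraction), and this keeps the studies
fast; 250 Hz remains the default for data-like output. The link-recovery
study draws from a population with slightly lower intercepts and
sensitivities (`N(8,4)`, `N(60,12)`, `N(5,4)`, noise SD 5) so that ratings
stay clear of the 100-point ceiling: scale censoring flattens curvature
and is a separate, known distortion that would otherwise confound a study
of link-form identifiability.

## What the simulator does and does not emulate

Passing recovery tests show the pipeline correctly identifies the
generative structure the simulator encodes: a quadratic force–rating law,
heterogeneous slopes, force-dependent failure, and linear
symptom–sensitivity couplings. Real data differ in ways the simulator does
not attempt: ratings are integer-ish and anchored, motor noise is neither
Gaussian nor stationary within a trial, fatigue accumulates across trials
(the simulator's trials are exchangeable given the schedule), and symptom
questionnaires have item structure. Results on simulated cohorts therefore
validate the *estimators*, not any empirical claim about effort
perception.

## Known limitations

* The exponential and hyperbolic link transforms are fixed parameter-free
  forms; a free steepness parameter would require nonlinear mixed models,
  which the BIC comparison framework here deliberately avoids.
* Ratings clipped at the scale bounds mildly bias first-level slopes for
  participants near ceiling; the rating-cap sensitivity analysis probes
  this but does not remove it.
* Second-level inference uses classical standard errors; no
  heteroscedasticity correction is applied at level 2.

## A worked run

```{r, eval = FALSE}
cfg <- effort_config(n_participants = 108, seed = 7)
run <- run_pipeline(cfg, out_dir = "effortsens-run")
run$preprocessed$counts
attr(run$link, "selected")
tidy(run$group_model)
summarize_group(run$ridge)
autoplot(run$ridge)
```
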