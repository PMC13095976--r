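# effortsens

Simulation and analysis of **perceived-effort sensitivity** in grip
force-matching experiments.

## The problem

In an isometric force-matching task, participants squeeze a hand
dynamometer to hold their force inside a narrow band around a target level
(20–100% of that hand's maximal voluntary contraction, MVC) for 3 s within
a 7-s window, alternating hands across 38 trials, and rate perceived
effort on a 0–100 visual-analogue scale after every trial. Two quantities
summarise each participant:

* **force sensitivity** — the slope of rating on squared force fraction,
  from a Huber robust regression
  `rating ~ f² + failure + hand`
  (a quadratic law is selected by BIC over linear, quadratic, hyperbolic
  and exponential transforms in linear mixed models);
* **failure sensitivity** — the same regression's coefficient on the
  failure indicator.

Second-level regressions relate these sensitivities to depressive (PHQ9)
and apathy (AES) symptom scores, z-scored, with sex, age and the
dominant/nondominant MVC ratio as covariates and Benjamini–Hochberg FDR
over the four symptom tests. A complementary two-step analysis — Huber trial
weights passed to a 10-fold cross-validated ridge regression — estimates
each participant's weighting of all trial features (target force, failure,
previous rating and target, cumulative force, force instability, initial
overshoot, excess force, hand).

The package is aimed at researchers designing or reanalysing effort
psychophysics experiments: every stage runs on simulated cohorts whose
statistical structure (quadratic ratings, force-dependent failure,
symptom couplings, the cross-hand MVC miscalibration and its correction)
is generated by the package itself, so estimator behaviour can be studied
end to end without any recorded data.

## Worked example

```r
library(effortsens)

cfg <- effort_config(n_participants = 108, seed = 7,
                     design = task_design(sample_rate_hz = 50))
run <- run_pipeline(cfg, out_dir = tempfile("effortsens-run"))
#> effortsens pipeline
#> config hash: 95f09a51ea6b9d8c81dd3e41d7af2d22
#> cohort: 108 participants, 4104 trials
#> preprocess: 108 -> 81 (top-quartile MVC ratio) -> 77 (outliers/all-success)
#> features: 2849 rows x 16 columns
#> link selection: exponential link, intercept_slope random effects
#> sensitivity: 77 participants; intercept-PHQ9 r = 0.330 (cap 90)
#> ridge: 77 participants, median lambda 0.494

run$preprocessed$counts
#>          input after_quartile after_outliers
#>            108             81             77

dplyr::filter(tidy(run$group_model), !is.na(q_value))
#> # A tibble: 4 × 7
#>   outcome       term  estimate std_error statistic  p_value  q_value
#>   <chr>         <chr>    <dbl>     <dbl>     <dbl>    <dbl>    <dbl>
#> 1 force_slope   phq9   -0.264      0.134    -1.97  0.0525   0.105
#> 2 force_slope   aes    -0.223      0.132    -1.69  0.0953   0.127
#> 3 failure_slope phq9    0.520      0.132     3.95  0.000184 0.000736
#> 4 failure_slope aes    0.0263     0.130     0.202  0.841    0.841
```

Reading the output: 108 simulated participants reduce to 81 after removing
the top quartile of MVC ratios (whose hands saw the most mismatched
targets under the cross-hand scaling error) and to 77 after the Spearman,
failure-proportion and all-success exclusions. The second-level
standardised coefficients carry the generative coupling signs — more
depressive symptoms go with lower force sensitivity and higher failure
sensitivity, with no positive apathy association — and the intercept–PHQ9
correlation is clearly positive. Two honest features of this particular
run are worth noting. First, with a single cohort the attenuated force
coupling (−0.26) just misses FDR significance; the dedicated recovery
study (20 cohorts, `scripts/acceptance.R`) shows the estimator recovers
the coupling sign in every run with mean absolute error well under 0.15.
Second, under the full study conditions many ratings sit at the 100-point
ceiling, and on this seed the exponential transform's BIC edges out the
quadratic; the methods vignette discusses why scale censoring blurs
link-form identifiability and why the link-recovery study therefore uses a
ceiling-free population (where the quadratic + random-slope cell wins
20/20).

Per-stage outputs (`trials.csv`, `exclusions.csv`, `features.csv`,
`link_comparison.csv`, `sensitivities.csv`, `group_model.json`,
`ridge_betas.csv`, `feature_correlations.csv`, `report.md`) land in
`out_dir`. `plot_rating_force()`, `plot_failure_force()` and the
`autoplot()` methods give the standard diagnostic figures.

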