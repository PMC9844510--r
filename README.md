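# bitrack

Tools for studying how two hands share a redundant continuous tracking
task. In the paradigm this package models, participants flex/extend both
wrists to steer a single cursor after a moving target while the hands are
coupled *visually* — the cursor shows the left wrist, the right wrist, or
their average — and/or *mechanically* — a virtual torsional spring
(K = 0.63 or 2.86 Nm/rad) or a rigid bar between the handles. The
scientific questions are how coupling type and stiffness redistribute
motion and muscular effort between the hands, and what they do to
tracking performance.

The package provides the full computational pipeline for such
experiments, with a seeded synthetic cohort standing in for raw
recordings (none are publicly deposited for this paradigm):

* **Task model** — the multisine target
  `q*(t) = −7.8 sin(0.48 t*) + 1.6 sin(1.12 t*) + 9.4 sin(1.48 t*) − 10.6 sin(2.56 t*)`
  (degrees, `t* = t + t0`), admissible zero-crossing start times, cursor
  weightings, and the spring coupling-torque law.
* **Cohort simulator** — both experimental protocols (18 participants ×
  6 within-subject conditions; four stiffness groups of 10 × 3 cursor
  weightings), 100 Hz wrist angles and 1000 Hz EMG/torque per 25-s
  trial, PD tracking control with signal-dependent motor noise, typical
  and atypical behavioral phenotypes, and isometric calibration
  recordings.
* **Signal processing** — the standard EMG envelope (20 Hz high-pass,
  rectify, 5 Hz low-pass, second-order Butterworth, zero-phase) and
  linear EMG-to-torque calibration.
* **Metrics** — per-trial normalized arc length (NAL), reciprocal
  activation `u_ra = max(|τf|,|τe|) − min(|τf|,|τe|)`, co-contraction
  `u_cc = min(|τf|,|τe|)`, left-minus-right imbalances, RMS tracking
  error, Spearman hand correlation; first-second trimming and
  last-five-trial aggregation.
* **Statistics** — Shapiro–Wilk screening, aligned-rank-transform (ART)
  factorial ANOVA for repeated-measures and mixed designs,
  random-intercept mixed-effects slope models (REML, Satterthwaite df),
  Wilcoxon/Mann–Whitney pairwise families with W/U and tie-corrected Z,
  and Hommel or Benjamini–Hochberg correction (BH beyond 24
  comparisons).

Everything is tidyverse-shaped: tables in, tibbles out, `tidy()` /
`glance()` on fitted objects, `plot_*()`/`autoplot()` for the standard
views.

## Worked example

Simulate the four-group stiffness protocol at a reduced size (four
participants per group), run the whole pipeline, and look at the
imbalance-versus-weighting slopes:

```r
library(bitrack)

res <- run_pipeline(pipeline_config("experiment2", n = 4, seed = 7))
cat(res$report)
#> # Bimanual tracking pipeline report
#>
#> - scenario: experiment2 (master seed 7)
#> - participants: 16; trials: 480
#>
#> - uncoupled unequal weighting: task-relevant hand NAL 1.00, task-irrelevant 0.30
#> - coupled conditions: minimum per-condition mean NAL 1.00 (both hands active)
#> - coupled effort imbalances (left - right): RA -0.001 Nm, CC 0.001 Nm
#> - median hand correlation by connection:
#>     - not_connected: 0.505
#>     - compliant: 1.000
#>     - medium_hard: 1.000
#>     - rigid: 1.000
#>
#> - inferential results: 60 rows, 4 with raw p < 0.05

imbalance_slopes(res$aggregated, "nal_imb")[,
  c("connection", "slope", "slope_df", "slope_t", "slope_p")]
#> # A tibble: 4 × 5
#>   connection        slope slope_df slope_t   slope_p
#>   <chr>             <dbl>    <dbl>   <dbl>     <dbl>
#> 1 compliant      0.000531     7.00    4.25  0.00379
#> 2 medium_hard    0.000425     7.00    4.30  0.00358
#> 3 not_connected -0.705       10.0    -4.91  0.000617
#> 4 rigid          0           10      NA    NA
```

The numbers tell the paradigm's story. With no mechanical connection the
task-irrelevant hand barely moves (NAL 0.30 on average here — the
"atypical" minority moves both hands and pulls the mean up from near
zero), so the arc-length imbalance swings strongly with the cursor
weighting: a large negative slope (−0.705 per weighting step, left coded
−1, center 0, right +1) that is clearly significant. Under any
mechanical coupling both hands track the target fully (NAL ≈ 1 for
every condition), the imbalance no longer depends on the weighting
(near-zero slopes), and the wrists move in near-perfect rank correlation
— exactly 1 under the rigid bar, which is a kinematic constraint rather
than a strong spring. Effort imbalances (RA, CC, in Nm) sit near zero in
the coupled groups.

A single trial, the metric table, or a fitted slope model can each be
inspected directly:

```r
co  <- generate_cohort("experiment1", seed = 1, n = 2)
met <- compute_metrics(co)            # one row per trial
agg <- trim_and_aggregate(met)        # one row per participant × condition
plot_metric_by_condition(agg, "rms_error")

m <- lme_slope(simulate_imbalance_cohort(20, slope = -0.15),
               "imbalance", "weighting_code", "participant")
tidy(m, conf.int = TRUE)
#> # A tibble: 2 × 8
#>   term      estimate std.error    df statistic  p.value conf.low conf.high
#>   ...
```

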