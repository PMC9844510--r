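---
title: "Simulating and analysing coupled bimanual tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing coupled bimanual tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

bitrack models a redundant bimanual task: two wrists jointly control one
cursor that has to track a moving target, while the hands are coupled
either *visually* (one shared cursor mapped to a weighted combination of
the two wrist angles) or *mechanically* (a virtual torsional spring, or a
rigid bar). The package provides the task model, a synthetic cohort
simulator, the EMG-based effort metrics, and the nonparametric /
mixed-model inferential layer that this kind of experiment uses. This
vignette explains the model, the defaults and the design decisions; the
README shows the worked end-to-end example.

## The task

The target is a multisine in degrees,

$$q^*(t) = -7.8\sin(0.48\,t^*) + 1.6\sin(1.12\,t^*) + 9.4\sin(1.48\,t^*)
  - 10.6\sin(2.56\,t^*),\qquad t^* = t + t_0,$$

over a 25-s trial. The four angular frequencies are all multiples of
0.04 rad/s, so the signal repeats every $2\pi/0.04 \approx 157.1$ s and is
odd in $t^*$. Two consequences matter for testing. First, the extremes
over one full period are exactly symmetric, $\pm 28.196^\circ$
(`target_range("period")`); over the domain a participant can actually
visit ($t^* \in [0, 50]$ s, since both $t$ and $t_0$ live in $[0,25]$ s)
the maximum is only $+25.270^\circ$ (`target_range("visualized")`).
Second, trials may start at any $t_0$ where the target crosses zero, so
cursor and target coincide at onset; `start_time_zeros()` locates the 18
admissible offsets by a 1-ms sign-change scan refined by bisection to
$10^{-6}$ degrees, and `sample_start_time()` draws uniformly from that
finite set. Ties are impossible: distinct zeros are separated by far more
than the scan step.

The cursor shows the left wrist, the right wrist, or their average
(`cursor_position()`). The virtual spring exerts
$K(q_r - q_l)\pi/180$ Nm on the left wrist and its negation on the right,
with $K$ = 0.63 (compliant) or 2.86 Nm/rad (medium-hard)
(`coupling_torque()`). Angles stay in degrees everywhere; radians appear
only inside the spring law, whose stiffness is per radian. Two modeling
choices are deliberately not taken from any published hardware
description:

* a small parallel damping term (default 0.05 Nm s/rad) accompanies the
  spring for integration stability; it is configurable and documented as
  an assumption, and it is applied only when a spring is active;
* the rigid bar is a kinematic constraint $q_l \equiv q_r$ on a single
  plant with summed inertias and viscosities, not a very stiff spring -
  a stiff-spring approximation at 1 kHz would either ring or force an
  implicit solver.

## The synthetic cohort

No public recordings exist for this paradigm, so the package's data are
synthetic by construction, and the simulator is first-class, tested code.
`generate_cohort()` reproduces the two protocols exactly: experiment 1 is
18 participants by six within-subject conditions (three cursor weightings
crossed with not-connected / medium-hard) in counterbalanced connection
order; experiment 2 is four groups of ten, one connection level per group
(not-connected, compliant, medium-hard, rigid), three weighting blocks
each. Every block holds ten 25-s trials; wrist angles are produced at
100 Hz (2,500 samples) and EMG and commanded torque at 1000 Hz (25,000
samples). Every trial draws its start time from the admissible zero set
and carries its own seed derived from the master seed, so a cohort is
byte-identical given the same configuration.

Each participant is a draw from `cohort_config()` distributions: a
laterality quotient truncated above 70 (a right-handed population),
per-hand proportional-derivative tracking gains, a preferred left-hand
share of the corrective command, per-hand tonic co-contraction torques,
per-hand signal-dependent noise multipliers (left - the nondominant hand
- noisier on average), per-muscle EMG gains (log-normal, V/Nm) and an
additive EMG sensor noise SD. A participant is "atypical" with
probability 4/18: in uncoupled unequal-weighting blocks, where one hand
cannot affect the cursor, a typical participant sends that hand no
command at all, while an atypical participant mirrors the task-relevant
hand's command - the two phenotypes observed empirically.

The trial itself integrates two second-order plants,
$I\ddot q = u + \tau_\text{couple} - b\dot q$, with semi-implicit Euler at
1 kHz and decimation of the angle series to 100 Hz. Inertia
(0.003 kg m^2) and viscosity (0.02 Nm s/rad) are configuration entries
with defaults chosen for stable explicit integration at this rate; they
are not measured quantities. The per-hand command is a PD feedback on
cursor-target error split by the participant's effort share; shares are
scaled so that the closed-loop gain of the cursor matches the single-hand
case (under center weighting each hand receives a share of a doubled
total, so the averaged cursor keeps the same bandwidth). Motor noise is
Gaussian torque noise whose SD grows with total muscle activation - the
magnitude of the net command plus the tonic co-contraction - so a noisier
hand wanders more even at rest. An optional ramp (`ramp_trials`, off by
default) lets the task-irrelevant hand's command decay over the first
trials of a block to emulate early exploration; the steady-state
behavior is the tested surface.

EMG synthesis is the one place where realism is required for the
processing chain to be exercised at all: a muscle's voltage is its
activation (positive part of the net commanded torque for the flexor,
negative part for the extensor, plus the co-contraction baseline on
both), multiplied by gain and by a band-limited 30-300 Hz carrier, plus
sensor noise. The carrier is normalized by its own envelope so that
envelope extraction recovers the modulating activation; without that
normalization, reconstruction error would be dominated by the carrier's
random amplitude rather than by the filter chain under test. Flexion is
positive throughout.

What the generator does *not* emulate: learning curves across blocks,
fatigue, EMG artifacts and crosstalk, reaction-time variability at trial
onset, and the absolute magnitudes of human effort. On the last point:
with the default plant, tracking torques are of order 0.01-0.1 Nm,
smaller than torques reconstructed from human EMG. All package metrics
and tests are either scale-free (ranks, correlations, arc-length ratios)
or scale-equivariant (RA/CC in Nm, mixed-model slopes), so passing tests
demonstrate the pipeline's correctness and calibration, not agreement
with human effort magnitudes. Separately, `simulate_imbalance_cohort()`
generates participant-level imbalance tables directly at a chosen slope
and noise level - that generator, not the physics, is what parameter-
recovery studies use, with its residual SD (0.24) set so that a slope of
-0.15 at n = 20 yields |t| near 4, the effect size such experiments
report.

## Signal processing

`emg_envelope()` is the standard chain: second-order Butterworth
high-pass at 20 Hz, full-wave rectification, second-order Butterworth
low-pass at 5 Hz. Filtering is zero-phase (forward-backward) by default
because all metrics are offline; a causal single-pass mode exists. Two
numerical choices are worth stating:

* **Cutoff correction.** A forward-backward pass squares the magnitude
  response, which would move the -3 dB point and attenuate a 50 Hz
  carrier by about 2.5 %. The design cutoffs are therefore pre-warped by
  $(\sqrt2 - 1)^{1/4}$ (high-pass lowered to 16.0 Hz, low-pass raised to
  6.2 Hz) so the *combined* response is -3 dB at the nominal 20 / 5 Hz.
  With the correction, a unit 50 Hz sine yields a steady-state envelope
  within 2 % of the rectified-mean value $2/\pi$; the remaining ~1.8 %
  is mostly the discretization of the rectified mean at 20 samples per
  cycle, not filter loss.
* **Edges and negativity.** Edges are handled by odd-reflection padding
  (half a second at 1 kHz); the first second of every trial is discarded
  downstream anyway. Small negative excursions from low-pass ringing are
  kept, not clamped, so the operator stays positively homogeneous
  (`envelope(a x) = a envelope(x)`); the effort metrics take absolute
  values regardless.

Calibration regresses torque on the envelope (`fit_calibration()`), so
predictions are in Nm; the opposite regression direction would predict
volts. Isometric recordings (`simulate_isometric_calibration()`) are a
ten-level staircase covering the task's torque range, stored at envelope
scale - the preprocessed muscle level a calibration session keeps - so a
noise-free recording recovers the gain to machine precision, and the
noisy default recovers it within a few percent. A constant-torque
recording is rejected (degenerate regressor), as is any envelope with
zero variance.

## Metrics

Per trial, after dropping the first second (2,400 angle samples, 24,000
torque samples): normalized arc length per hand (path length over target
path length, raw 100 Hz differences, no extra smoothing - smoothing
would silently rescale it); reciprocal activation
$u_{ra} = \max(|\tau_f|,|\tau_e|) - \min(|\tau_f|,|\tau_e|)$ and
co-contraction $u_{cc} = \min(|\tau_f|,|\tau_e|)$, which satisfy
$u_{ra} + 2u_{cc} = |\tau_f| + |\tau_e|$ identically; RMS cursor-target
error; and the Spearman correlation between the wrists. The trial scalar
for RA and CC is the *time mean* over the analysis window rather than
the integral, so values are duration-independent - the field reports
scalar comparisons without stating which; the mean is this package's
convention and is flagged as such. Imbalances are left minus right,
exactly. Angle metrics live on the 100 Hz grid and torque metrics on the
1000 Hz grid; nothing is resampled across rates. `trim_and_aggregate()`
keeps trials 6-10 of each block and averages per participant and
condition - the steady-state summary used for inference - and refuses
incomplete blocks.

## Statistics

*Normality screening* is Shapiro-Wilk per condition cell (3-5000
non-constant values; degenerate cells are an error naming the cell).

*ART ANOVA.* `art_anova()` implements the aligned rank transform for
factorial designs: for each effect, subtract the cell-mean estimates of
every other effect (inclusion-exclusion over marginal means, using cell
means, not medians), rank the aligned responses with average ranks, and
run the factorial ANOVA on the ranks with the subject as the error term
for within-subject factors (`aov` with an `Error(subject/...)` stratum;
between-subject effects are tested against subjects). In within-subject
and mixed designs the per-subject offset is also removed during
alignment, measured about the subject's between-group cell where one
exists. Only the target effect's row of each aligned fit is reported.
The implementation check is the classic one - after aligning for an
effect, a factorial ANOVA on the *unranked* aligned response shows
(near-)zero sums of squares for every other effect - and the suite also
verifies nominal type-I error (within [0.03, 0.07] at $\alpha = 0.05$ on
null 2x3 within designs with n = 18, 1000 replicates) and decision
agreement with the signed-rank test on one-factor two-level designs.

*Mixed-effects slopes.* `lme_slope()` fits a per-subject random
intercept with one fixed slope by REML via lmerTest, reporting
Satterthwaite approximate degrees of freedom; every result records its
`df_method`. Degenerate inputs take documented detours: a constant
response returns a slope of exactly zero; a response perfectly explained
by subject dummies plus the slope (zero residual variance) and a design
with one observation per subject both fall back to ordinary regression
with residual df, with a warning. The cursor weighting is coded center
= 0, right = +1, and left = -1 - only the first two are fixed by
convention elsewhere; the symmetric -1 is this package's choice so the
slope means "per step toward the right-favoring cursor". The trial-trend
model (`trial_trend()`) is the same machinery with the trial number as
regressor over the first or last five trials.

*Pairwise families.* Three tailored families (`pairwise_family()`):
weighting pairs within each connection level (paired), connection pairs
within each weighting (paired within-subject designs, unpaired across
groups), and left-versus-right per condition cell (paired). Paired
comparisons use the Wilcoxon signed-rank statistic W with zero
differences dropped and average ranks on ties; unpaired use
Mann-Whitney U. Both report the tie-corrected normal-approximation Z and
its two-sided p, so W/U and Z are jointly reportable; an all-zero
difference vector is flagged undefined rather than silently p = 1 (the
rigid group's left-versus-right NAL comparison is the canonical case).
Families of up to 24 comparisons are Hommel-adjusted, larger families
Benjamini-Hochberg (`choose_correction()`); both adjustments dominate
the raw p-values and preserve their order.

## Problem sizes and runtime choices

The simulation studies in the test-suite and acceptance script use: the
full experiment-2 protocol (four groups of ten, 1,200 trials) for
behavioral-pattern recovery, simulated without EMG synthesis since only
kinematics enter those metrics; 200 replicates for slope-recovery
coverage and 400 for null false-positive rates at n = 20 subjects; 1,000
replicates for ART type-I calibration at n = 18; and 10^4 random
families for the multiplicity checks. Unit tests run on two-participant
cohorts, which exercise every code path at a fraction of the cost.

## Known limitations

* The plant and controller are deliberately minimal (no muscle dynamics,
  no feedforward prediction, no learning); the simulator targets the
  *qualitative* steady-state pattern - task-irrelevant hand quiet only
  when uncoupled, both hands active under any coupling, hand correlation
  growing with stiffness - not trajectory-level realism.
* Synthetic effort magnitudes are smaller than human EMG-derived
  torques (see above); only scale-free or scale-equivariant conclusions
  transfer.
* Satterthwaite degrees of freedom come from lmerTest's implementation;
  a residual-df fallback covers the degenerate fits, and `df_method`
  always says which was used.
* The Hommel adjustment is taken from `stats::p.adjust` and is checked
  by its defining properties (domination, monotonicity), while BH is
  additionally checked against a brute-force step-up oracle.
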