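---
title: "Models and methods behind pathintlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pathintlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pathintlab` implements, end to end and on synthetic data, the analysis
pipeline of a virtual path-integration experiment of the "apple game"
type: participants walk from a goal (basket) along a chain of one to
five trees and must then return to the remembered goal with no outward
aids (pure path integration, PPI), with a circular boundary wall (BPI),
or with an intramaze landmark (LPI). This vignette explains the models
the package implements, the choices that were genuinely open, and what
the synthetic generators do and do not emulate.

## The task and its geometry

The arena is a disc of radius 6788 virtual meters (vm). Distances are
anchored to real space through the avatar's eye height: 310 vm
correspond to about 1.65 m, so the ~13,576 vm diameter is a ~72 m
arena (`vm_to_meters()`). Goals and trees are balanced on an invisible
8 x 8 grid of 800 vm squares: each 16-trial block uses the 16 goal
cells and 48 tree cells so that all 64 squares are visited exactly once
(`generate_trial_set()`; the tree composition is 1 tree x 3 trials,
2 x 3, 3 x 4, 4 x 3, 5 x 3). Locations are placed at cell centers,
which makes the design arithmetic exact: the largest possible
retrieval-to-goal (incoming) distance is the grid diagonal,
`sqrt(2) * 5600 = 7920` vm, about 58% of the arena diameter.

Movement is speed-limited in the outer ring: beyond a radius of 5657 vm
the speed factor falls linearly to zero at 6788 vm, but only when
heading away from the center (`speed_factor()`). The original
description states the rule qualitatively; we operationalize "heading
toward the center" as a negative radial velocity component and switch
binarily between the two regimes. After each trial, the drop error
(response-to-goal distance) is scored with zero to three stars using
strict thresholds (<1600, <3200, <6400 vm).

## The synthetic navigator

There is no accepted generative model of human path-integration error,
so the agent (`simulate_trial()`, `simulate_cohort()`) is a
deliberately simple noisy dead-reckoning process whose *statistical
signature* matches what the analysis assumes:

* The agent's true position is under perfect control (as a joystick
  is), but its internal position estimate integrates noisy copies of
  each 200-ms displacement: heading noise (Gaussian, SD
  `heading_noise_sd` degrees per step, default 10) and multiplicative
  step-length noise (CV `step_noise_cv`, default 0.15). Homing error
  therefore grows with path length -- the error-accumulation property.
* During the incoming phase the agent steers toward its internal goal
  estimate. When a cue is visible, the estimate is pulled toward truth
  once per second by a fraction `kappa` (`cue_gain_boundary` = 0.3,
  `cue_gain_landmark` = 0.5 by default); the landmark correction is
  weighted by proximity, `halfsat / (halfsat + distance)` with
  `halfsat` = 2000 vm, so performance degrades with goal-to-landmark
  distance.
* The agent rotates in place at `turn_speed` (90 deg/s) between legs,
  with zero translational speed while turning -- as joystick navigation
  does. This matters downstream: the slow-movement exclusion of the
  imaging pipeline is exactly what removes turn-dominated volumes.
* Cohorts add lognormal subject- and site-level heterogeneity (SDs 0.2
  and 0.1 on the log scale) to the noise parameters, a bimodal age
  mixture (24 +/- 5 and 59 +/- 8 years, mixing 0.61/0.39) so the
  k-means age split has realistic input, and a risk group whose heading
  noise is 1.5x the control value. Because cue correction removes
  accumulated error in BPI and LPI, this single group parameter plants
  the qualitative signature of interest: a group deficit specific to
  the cue-free subtask.

Defaults are in `agent_params()` and were chosen once for plausibility
(cruise speed 1000 vm/s gives behavioral-experiment pacing; for
fMRI-style runs we simulate at 250 vm/s so a trial lasts tens of
seconds, matching ~22-minute runs of 24 trials). The agent is not a
cognitive model: it has no systematic biases (e.g. no leaky
integration or boundary compression), no learning across trials, and
its errors are unbiased around the goal. Passing recovery tests on
these data shows the *pipeline* is correct, not that real human data
would behave this way.

## Behavioral metrics and models

`compute_trial_metrics()` implements the error measures: drop error
(response to goal), distance error `|D_correct - D_response|`, rotation
error (absolute angular difference of the correct and chosen incoming
headings; the signed difference is analyzed as a magnitude, wrapped to
[0, 180]), outgoing distance (cumulated leg sum), and
incoming distance (retrieval-to-goal Euclidean distance), plus the
goal-to-cue and movement-to-cue distances (the latter averaged over all
incoming-phase samples). For readability, errors are mapped onto a
0-1000 performance scale by the linear, order-reversing transform
`(max - e + min) / max * 1000`, normalized per error type across the
whole dataset; the transform changes no statistics.

The mixed-model layer (`build_model_spec()`, `fit_lmm()`) mirrors the
study's declarative model table: subtask and one path-distance
predictor within subjects, genotype (and, in models 3-5, a regional
volume) between subjects, age and sex as covariates, random intercepts
for subject and site. Continuous between-subject predictors are
centered on the grand mean, within-subject predictors on the subject
mean; each continuous within-subject predictor also receives
equal-count rank bins (quintiles by default, `quantile_bins()`) for
post-hoc contrasts.

Fixed terms are tested with type-II Wald chi-square statistics
converted to F with a containment-style approximation of the
denominator degrees of freedom: terms built only from between-subject
variables are tested against `n_subjects - p_between - 1`, all others
against `n_obs - n_subjects - p_within`. This choice keeps the test
order-invariant and calibrated (the null rejection rate of the group
term sits at ~4-5% in simulation) without the heavy refitting that
finer df approximations require; random slopes are not fitted because
the design names random *factors* only. When no usable random
structure exists, `fit_lmm()` falls back to ordinary least squares with
exact type-II F tests (in which case the two-group F equals the squared
two-sample t). Pairwise post-hocs use Tukey adjustment through the
studentized-range distribution (`tukey_adjust()`, which matches the
`emmeans` machinery on balanced families and is slightly conservative
otherwise).

The exploratory model buildup (`model6_buildup()`) walks candidate
between-subject predictors in priority order and (1) drops any
candidate significantly correlated with an already-kept one at the
subject level (alpha = 0.05; "significantly correlated" needs a fixed
rule, and significance at the conventional level is the one adopted
here), (2) screens each survivor's main effect at alpha = 0.1, and
(3) backward-eliminates the highest-order nonsignificant terms at
alpha = 0.05, allowing candidate-by-subtask and candidate-by-distance
interactions but never candidate-by-candidate ones. On planted data
this recovers a single active predictor, and only it, in >= 90% of
datasets.

## Cohort statistics

Allele frequencies use Mendelian counting (two alleles per subject)
standardized by `N_allele = 2 * N_genotype`; genotype prevalences are
standardized by subjects -- the distinction that makes an allele
frequency half the prevalence of the corresponding carrier genotypes.
Contingency comparisons use the uncorrected Pearson chi-square: the
printed statistics are reproduced exactly without continuity
correction, and not with it. The data-driven age split is
one-dimensional k-means with k = 2 and ten seeded restarts, with the
cutoff defined as the minimum age of the older cluster (so "older"
means age >= cutoff); a two-valued age vector is split directly by
value, which is the exact 2-means solution.

## The grid-code imaging pipeline

`simulate_grid_bold()` plants an n-fold directional signal in a
multi-voxel region: voxel `v` has neural activity
`A * cos(s * (theta(t) - phi_v))` while the agent translates (zero when
standing or turning), with preferred phases `phi_v` drawn uniformly.
Optional parametric-modulator responses can be added per voxel. The 5
Hz neural series is convolved with the canonical double-gamma HRF
(gamma(6,1) response minus gamma(16,1)/6 undershoot; peak at 5 s, zero
at onset), averaged into TR = 2.5 s volumes by sample midpoint (a
volume is 12.5 samples, so midpoint assignment is what keeps the
volume grid exact), and white Gaussian noise is added. Drift, motion,
and physiological noise are deliberately not modeled.

The analysis (`glr_contrast()` and its stages) follows the
pattern-similarity logic: annotate each volume with the circular mean
movement direction and mean speed of the 200-ms samples that caused
its signal, exclude volumes below 33% of the mean movement speed,
average volume patterns within 5-degree direction bins, correlate bin
patterns across voxels (Fisher z, |r| capped at `1 - 1e-12`), drop bin
pairs that share a trial, and contrast mean similarity at angular
differences within 15 degrees of a multiple of 60 against the
30-degree-offset condition. Control symmetries (4, 5, 7, 8) scale the
window with the period (+/- P/4, the natural generalization of +/- 15
degrees at sixfold; boundary values count as aligned, a documented tie
rule). One analysis parameter deserves emphasis: volumes are annotated
with behavior shifted by `hrf_lag` (default 5 s, the HRF peak), because
the signal in a volume reflects movement one hemodynamic delay earlier;
with `hrf_lag = 0` a planted signal is invisible to the pipeline on any
trajectory whose heading changes on the TR timescale. Directional
sampling is checked with a Rayleigh test against a uniform-resampling
surrogate distribution (in 360-degree and 60-degree space), and
`snr()` provides the temporal/spatial signal-to-noise summaries.

Because bins average volumes *across* trials, the same-trial exclusion
is implemented as removing bin pairs whose contributing-trial sets
intersect; with many trials per bin this removes most close-in-time
pairs, which is its purpose.

## Parametric GLMs

`build_modulators()` computes integrated path (within-phase cumulative
distance, nondecreasing) and goal distance (instantaneous distance to
goal) at 5 Hz, min-max normalized to [0, 1] and mean-centered per
phase. `build_design()` assembles the three first-level designs: the
PI model (start / outgoing / incoming / no-movement regressors per
subtask, movement regressors as zero-duration onsets at every 200-ms
sample, one modulator on each movement regressor), the subtask model
(phase boxcars plus a 1-5 tree-count difficulty modulator on the
outgoing phase), and the combined model, in which goal distance enters
first and integrated path is orthogonalized against it column-wise
after convolution -- orthogonalization leaves the first modulator's
estimate untouched. "No movement" is speed at or below the subject's
1st percentile. Runs are estimated separately and stacked blockwise
(`combine_run_designs()`; the two-run PI model has 24 base
regressors). Estimation is ordinary least squares on the ROI mean (or
per voxel) with named-weight contrasts; temporal derivatives are not
modeled.

`modulator_correlation_test()` mirrors the two-level surrogate logic:
per subject, Spearman's rho between the two modulator series against a
time-shuffle null, the one-sided rank p mapped to a z value; at the
group level the mean z is tested against sign-flip surrogates. Goal
*proximity* is the negated goal distance; the `proximity` flag flips
the reported sign, which is worth keeping explicit because the two
conventions differ only in sign.

## Problem sizes, tolerances, and degenerate inputs

The test suite verifies exact arithmetic (allele frequencies,
chi-square statistics, design counts, unit conversion) at printed
precision, and stochastic properties at desk scale chosen once:
planted-signal recovery on ~48-trial runs with 30 voxels (noiseless
recovery must hold for every seed; 60-seed white-noise nulls must stay
within 2 SE of zero at all symmetries), the genotype-by-subtask
recovery on 20 cohorts of 200 subjects (>= 90% must show a significant
interaction with the cue-free-specific direction), 500-replicate
calibration of the mixed-model group test and 800-replicate
calibration of the Rayleigh surrogate test (both within [0.03, 0.07]
at nominal 0.05), and 200-replicate GLM recovery of a planted
modulator effect (mean within +/- 0.1 of truth). Surrogate counts in
tests are in the hundreds for runtime; function defaults remain
10,000.

Degenerate inputs are signaled, not silently absorbed: over-exclusion
in the recruitment audit, all-zero genotype tables, zero cohort-maximum
error in the performance transform, constant modulator series,
rank-deficient designs (with the collinear columns named),
zero-variance patterns, responses coinciding with the retrieval
location (rotation error undefined), and all-identical ages.

## Known limitations

* The agent is a statistical stand-in; none of its parameters were
  fitted to human data, and effect sizes on synthetic cohorts have no
  quantitative relation to effect sizes in any human cohort.
* The containment df approximation is coarse for strongly unbalanced
  designs; it was chosen for order-invariance and calibration, not
  small-sample exactness.
* The imaging simulator omits anatomical structure entirely (no ROI
  geometry, no subregion gradients, no spatial noise correlation), so
  hemisphere- or subregion-specific questions cannot be posed to it.
* The Tukey adjustment uses the studentized-range bound rather than
  exact multivariate-t integration for unbalanced families.
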