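---
title: "Robotic proprioception and visuomotor-adaptation assessment: models and methods"
author: "proprioadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robotic proprioception and visuomotor-adaptation assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`proprioadapt` implements the analysis chain of a robotic (Kinarm-style)
upper-limb assessment battery for stroke survivors: two bimanual
proprioception tasks (arm position-matching, APM; arm movement-matching,
AMM), a visuomotor rotation task (VMR), normative task scoring with
impairment classification, and the statistics relating proprioceptive to
adaptation impairments. Patient-level recordings from such batteries are
generally not shareable, so the package ships a synthetic-cohort
generator whose draws have the statistical structure the analysis
assumes; everything downstream operates identically on real long-format
trajectory tables.

# Tasks and kinematic conventions

All positions live in a planar workspace: x rightward, y away from the
body, metres, with the participant midline at x = 0. Mirroring the active
arm into the passive arm's frame is the reflection `x -> 2 * midline - x`.

Robot-guided passive movements follow the minimum-jerk polynomial
`s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`, the standard model for smooth
bell-shaped reaches. Its analytic peak speed is `15/8 * distance /
duration`, which is how movement durations are chosen to hit the
protocol's passive peak speeds (0.283 m/s on average for the 10 cm APM
moves, participant means drawn uniformly in 0.167-0.406 m/s; 0.20 m/s
for the 20 cm AMM moves).

Velocity is obtained by central differences without smoothing: synthetic
trajectories are noise-free in position, and fixing the differentiation
scheme keeps results reproducible. A zero-phase moving-average position
smoother (`smooth_position()`) exists as an opt-in hook for real
recordings and is off everywhere by default.

Movement onset is the first sample at which the velocity signal strictly
exceeds 12.5% of its peak - the forward (+y) velocity component for VMR
reaches, hand speed for the matching tasks. Onset is an index-like event,
so no interpolation is applied at the crossing; the initial reach
direction, in contrast, is probed at a continuous time (150 ms after
onset) and the probe position is linearly interpolated between samples.
Directions in the VMR task are signed relative to the straight
start-target line, positive in the direction that compensates the
counter-clockwise cursor rotation, so complete adaptation to the 30 deg
rotation reads +30.

# Proprioception metrics

APM (9 targets in a 3x3 grid, 10 cm spacing, 6 pseudorandomized blocks,
54 trials) yields, with matched positions mirrored into the passive
frame:

* **AE** - mean absolute matching error per direction, combined across
  x/y by root-sum-square;
* **Var** - trial-to-trial variability: the SD of matched positions
  across the 6 repetitions of each target, averaged over targets (a
  per-location quantity, not a pooled variance);
* **Area** - convex-hull area of the 9 per-target mean matched positions
  over the hull of the 9 targets. The hull-of-means construction is one
  of several possible readings of "area covered by the matched
  positions"; it is deterministic and scales exactly as the square of a
  uniform contraction, which the tests exploit;
* **Shift** - the mean matched-minus-target displacement.

AMM (20 cm movements between three triangle targets, 36 trials) compares
the active to the passive arm per trial: response latency RL (difference
of 12.5% onsets), peak-speed ratio PSR, initial-direction error IDE
(absolute direction difference at peak speed, wrapped to [0, 180]), and
path-length ratio PLR, averaged over non-failed trials. The battery's
source material does not define trial failure; here a trial fails when
the active trace has no detectable onset or its path length is under 25%
of the passive path. Failed trials are counted and excluded.

# Normative task scores

The scoring chain converts a participant's metric vector into one global
task score per task:

1. per-variable z-scores against a normative cohort (variables
   decomposed into x/y where applicable);
2. one-sided variables - those where only large values are abnormal (AE,
   Var; RL, IDE) - are mapped through `p = Phi(z)` to a **zeta score**
   `zeta(p) = Phi^{-1}((1 + p) / 2)`, so the best attainable score is 0
   and the normative 95th percentile maps to 1.96. Two-sided variables
   (Area, Shift; PSR, PLR) stay as z-scores;
3. root-sum-square (RSS) across the variable scores;
4. the RSS is renormalized to a z-score via a one-parameter Box-Cox
   transform (`lambda` fitted by profile maximum likelihood on the
   normative cohort's positive RSS values, shift-free since continuous
   noise keeps RSS > 0), then converted to a final zeta score;
5. a task score above 1.96 - outside 95% of the normative range - flags
   impairment. The cumulative probability is clipped to `1 - 1e-12`
   before the final zeta so extreme participants receive large finite
   scores.

The commercial battery computes these scores against a proprietary
normative database with demographic adjustment; those reference data
cannot be shipped, so models here are fitted on a synthetic normative
cohort generated in-repo (n = 120 by default, minimum 40), and scores
are comparable within a run, not to published patient scores. An
optional linear demographic adjustment (`metric ~ age + sex +
handedness`, z-scores from residuals) is exposed but off by default.
The AMM failed-trial count is part of the metric bundle but excluded
from the default score-variable list: synthetic controls essentially
never fail a trial, so its normative SD is zero and a z-score is
undefined; real datasets with control failures can add it back via the
`variables` argument.

# Visuomotor adaptation

Sessions have 25 baseline, 125 adaptation (30 deg counter-clockwise
rotation) and 25 washout trials. Summaries: baseline mean/SD; **Initial
Adaptation** and **Final Adaptation**, the mean initial direction of the
first and last 15 adaptation trials; and **Trials to Adapt**, the first
adaptation trial starting a run of 15 consecutive trials strictly above
a threshold, where the threshold is the lower bound of the controls'
95% range for Final Adaptation. The run must fit inside the adaptation
phase (latest admissible start 111) and failure scores 125.

"95% range" is read as empirical coverage - the 2.5th/97.5th percentiles
with R's default (type 7) interpolating quantile - rather than
mean +/- 1.96 SD. Classification is strict: Initial/Final Adaptation
below the lower bound, Trials to Adapt above the upper bound; values
exactly at a bound are not impaired; a participant is
adaptation-impaired if any of the three flags fires.

A structural property worth knowing: because the Trials-to-Adapt
threshold is fitted on the same controls, roughly 2.5% of controls sit
below it by construction and score the 125 ceiling. With 40 controls the
empirical 97.5th percentile then interpolates next to the ceiling, and
in a minority of synthetic cohorts it equals 125, in which case the
trials flag cannot fire and adaptation impairment is carried by the
Initial/Final flags alone. This is a property of the empirical-range
criterion with noisy trial series, not of the implementation.

# The synthetic cohort

The generator is first-class, tested code. Each participant is a
parameter bundle (`participant_params()`) driving all three tasks
deterministically from a per-participant RNG stream fanned out from the
master seed with a fixed affine map, so enlarging a cohort never changes
its leading participants.

* **APM**: matched position = mirrored target, contracted by `c` about
  the mirrored centroid, translated by a systematic shift, plus
  isotropic Gaussian matching noise. Contraction, shift and noise map
  one-to-one onto Area (`c^2`), Shift and AE/Var.
* **AMM**: the active arm reproduces the mirrored passive movement with
  a response latency, scaled peak speed, scaled path length and a
  Gaussian direction error; the active movement is timed so its 12.5%
  onset trails the passive one by exactly the latency, making RL
  recoverable to one sample step. Inter-trial delays are irrelevant to
  the metrics and omitted from the trial clock.
* **VMR**: a linear state-space learner, the de-facto standard
  trial-by-trial adaptation model: internal state
  `x_{t+1} = a x_t + b e_t`, error `e_t = r_t - x_t`, rotation `r_t` =
  30 deg during adaptation and 0 elsewhere; observed direction
  `y_t = x_t + N(0, sigma^2)` with i.i.d. execution noise. Asymptotic
  compensation is `30 b / (1 - a + b)`.

Control draws come from one healthy hyper-distribution. Its defaults
were fixed once, for realism, and the tests run against them: matching
noise ~ 9 mm, contraction near 1, shifts ~ 1 cm, latency ~ 150 ms,
speed/path ratios near 1, direction errors ~ 4 deg, execution noise ~
2 deg. Healthy learners are parametrized by their adaptation asymptote -
most compensate 24.5-30 deg, with a 5% weak-adapter tail reaching
16-24 deg, matching the spread visible in published control
distributions - and retention follows from the asymptote and learning
rate.

Stroke participants are a mixture: with probability 0.58 they receive
the proprioception-impaired parameter set (noise inflated 2-5x,
contracted and shifted workspace, 100-350 ms extra latency, degraded
speed/direction/length matching) and with probability 0.52 the
adaptation-impaired set (learning rate drawn in [0, 0.02]); the two
assignments are independent by default - the battery's empirical finding
motivates that default, but a Gaussian-copula correlation parameter is
exposed rather than asserted. All stroke participants additionally carry
a +3.27 deg elevation of execution noise, the group-level baseline-SD
difference reported for such cohorts, so the group comparison recovers
it. The ordinal TLT score (0-3) is derived from the proprioceptive-noise
latent through a monotone link with jitter, making it a noisy clinical
correlate of the same construct, never a computed output.

What the generator does **not** emulate: temporally autocorrelated
execution noise, corrective submovements, curved matching paths, fatigue
or time-on-task drifts, joint-space kinematics, and any demographic
dependence of the metrics. Passing tests therefore demonstrate that the
measurement and scoring chain is correct and calibrated under the
model's assumptions - not that it is robust to every property of real
recordings.

# Statistics

* **Bootstrap mean-difference tests** resample each group with
  replacement (99,999 resamples by default), report the percentile
  2.5/97.5 interval, and compute p as the percentile-of-zero with a +1
  continuity correction (minimum attainable two-tailed p =
  `2 / (n_boot + 1)`); the source material states only the resample
  count, so the p-value construction is this package's documented
  choice. Group adaptation comparisons are one-tailed in the direction
  of the clinical hypothesis (stroke adapts less, needs more trials);
  age and baseline comparisons are two-tailed.
* **Spearman correlations** use midranks, a t-approximation for p
  (adequate at cohort sizes ~ 45, in place of exact permutation), and a
  paired percentile-bootstrap CI. Partial Spearman rank-transforms all
  three variables and applies the first-order partial-correlation
  formula, covering the covariate-controlled analyses.
* **Fisher's exact test** (via `stats::fisher.test`) uses the
  probability-mass two-sided rule; the reported odds ratio is the sample
  `ad/bc`, with empty-cell extremes surfaced as 0/Inf rather than
  hidden.
* **Chi-squared** on sex composition is Pearson's on the 2x2 without
  continuity correction; on the published counts (22/40 vs 18/48) this
  gives X2 = 2.695, p = 0.101, and the 17.5% proportion difference.
* **Bonferroni-Holm** correction is applied within each correlation
  family and to the Fisher-test family.

Every stochastic routine takes an explicit seed; the pipeline fans seeds
out with a counter-based scheme so adding an analysis never shifts the
streams of earlier ones.

# Numerical choices and degenerate inputs

Quantiles are R type 7 throughout (documented because the
trials-to-adapt threshold depends on it). Onset uses strict exceedance
and first-sample semantics. Zero-SD normative variables, all-failed AMM
trial lists, constant correlation inputs, non-positive RSS under the
Box-Cox fit, and control ranges with fewer than 20 values all raise
typed errors rather than propagating NaN; a constant control range
warns. Probability clipping bounds the final zeta score at ~7.1.

# Problem sizes

Default study-sized runs (48 stroke, 40 controls, 120 normative,
full trajectory simulation) complete in well under a minute on one core
with reduced bootstrap counts; the package's own test-suite simulations
use 200-participant recovery cohorts, 500-replicate type-I calibration
at 2,000 resamples, and full Fisher enumeration for tables up to total
30. These sizes were chosen so each estimate's Monte-Carlo error is far
inside the tolerance it is checked against.
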