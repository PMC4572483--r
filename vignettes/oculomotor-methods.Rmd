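---
title: "Methods: oculomotor metrics and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oculomotor metrics and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazemetrics)
```

This vignette documents the models, numerical choices and open design
decisions behind the package, in the spirit of a methods section: what is
computed, under which assumptions, and what a passing test does and does
not establish.

## Event detection

Gaze speed is the Euclidean norm of the central-difference velocity of the
(x, y) position signal; acceleration is the central difference of speed;
endpoints use one-sided differences. A saccade is a maximal run of samples
with speed > 30 °/s or |acceleration| > 8000 °/s². These thresholds are the
standard commercial-parser settings for 250 Hz video-oculography and are
the package defaults (`default_config()`), configurable per run.

The vendor parsers this scheme emulates apply proprietary smoothing and
minimum-duration rules that are not published. We therefore document ours
instead of guessing theirs:

* no pre-smoothing of the position signal by default (a centred
  moving-average option, `smooth_window = 3`, exists);
* `min_saccade_duration_ms = 8` (two inter-sample intervals) suppresses
  single-sample noise triggers;
* `min_fixation_duration_ms = 40` keeps sub-threshold residue between
  events from being reported as fixations — the residue is retained
  separately so that saccades, fixations, blinks and residue tile the
  trial exactly (a tested invariant);
* blink spans (runs of invalid samples) are padded by 50 ms on each side,
  harmonised with the pursuit exclusion window;
* a saccade interrupted by a blink is kept as a single event flagged
  `contains_blink`, because several metrics exclude blink-contaminated
  saccades explicitly rather than at parse time.

**Event boundary positions.** The threshold run excludes the sub-threshold
tails of the velocity profile (for a 1.5° saccade roughly 20 ms on each
side), so taking the run's first/last samples as start/end systematically
underestimates amplitude — badly so near the detection floor where
square-wave-jerk classification needs amplitudes accurate to a few tenths
of a degree. Start and end positions are therefore measured as the mean
position over a short window (samples 6–11) just outside the run, which
skips the tail and averages sample noise. During smooth pursuit this
window adds a small amount of pursuit motion to measured amplitudes
(~0.3–0.6° at peak target velocity); this only affects the >2° saccade
count threshold in the conservative (inclusive) direction.

## Fixation-stability metrics

A square-wave jerk (SWJ) is a saccade of amplitude < 2° that takes gaze
*away* from the target, followed within 300 ms by a saccade of similar
amplitude (difference < 0.75°) taking gaze *back towards* it. Three points
are under-determined by that verbal rule and fixed here:

* *away/towards* is operationalised by comparing start- versus end-point
  distance to the target — direction-agnostic and robust for oblique
  micro-movements;
* the 300 ms interval runs from the *offset* of the first saccade to the
  *onset* of the second (`swj_interval_anchor` switches to onset→onset);
* pairing is greedy left-to-right and each saccade joins at most one SWJ,
  so rapid oscillations are not double counted; a return saccade cannot
  also open a new SWJ. The counter is property-tested against an
  independent brute-force pair scan.

SWJ components are not excluded from any other count (they are all < 2° so
the question only matters in principle). Large intrusive saccades are
blink-free saccades > 2°; the longest fixation period is the maximum
inter-saccade interval across the scored trials, capped by trial
boundaries.

## Saccade-task metrics

The first major saccade is found by removing saccades that contain a
blink, start before target onset, start more than 2.5° from the central
fixation point, or are misdirected by more than 45° (angle between the
displacement vector and the *centre*→target vector — the nominal centre,
not the saccade's own start point, since start points can already be
displaced and the 2.5° rule bounds the discrepancy). The first survivor is
kept; the trial is discarded if that survivor is the sixth parsed saccade
or later, counting *all* parsed saccades from trial start (the rule says
"the sixth saccade", not "the sixth candidate"). The filter rules are
independent predicates, so their application order is irrelevant (tested).

Anticipatory responses are removed by the started-before-target rule taken
literally: in gap trials, saccades launched during the 200 ms gap are
removed because target onset is the reference point.

Time to first fixation upon target uses the fixation's *mean* position for
the 2.5° test; a qualifying fixation already ongoing at target onset
yields 0 ms (clamped, never negative). No minimum-duration requirement is
imposed beyond the parser's 40 ms floor — the online trial-termination
criterion (250 ms within 1.5°) belongs to the task program, not the
analysis.

Both timing metrics are square-root transformed and trimmed at ±2 group
standard deviations (sample SD, n−1) after transformation. The trim is
skipped with a warning for groups with fewer than 3 observations, and is a
no-op for zero-variance groups. Note a small-sample fact the tests
exercise: with the n−1 SD the largest attainable |z| is (n−1)/√n, so no
point can be trimmed from groups of five or fewer observations.

## Pursuit metrics

The target moves as A·sin(2πft) with A = 10°, f = 0.25 Hz (2.5 cycles per
10 s trial), starting at centre; velocity is the analytic derivative.
Instantaneous gain is the *signed* along-axis eye velocity divided by
target velocity — the signed convention preserves direction reversals as
negative gain, which the [−1, +2] retention band presupposes. Samples
inside saccades, blinks or occlusions (±50 ms) are removed, gains outside
[−1, +2] are trimmed, and the per-trial mean is taken over what remains.

Two numerical guards are defaults rather than part of the verbal
procedure, both configurable to 0/off to reproduce it literally:

* samples with |target velocity| < 2 °/s (the sinusoid's turnarounds) are
  dropped before trimming, because the instantaneous ratio is unbounded
  there;
* the velocity estimate for gain uses the 3-sample pre-smoother
  (`gain_smooth_window = 3`). With noisier velocity estimates the
  asymmetric [−1, +2] band truncates the ratio distribution unevenly
  around gains near 1 and biases the mean down by up to ~0.1; with the
  smoother the recovery bias is ≤ ~0.03 across gains 0.5–1.0, inside the
  ±0.05 tolerance the recovery tests assert.

## Group statistics and classification

The models are ordinary least squares on per-trial observations —
(transformed) metric on group + age, plus eccentricity and gap/overlap
condition for saccade metrics, saccade amplitude for peak velocity, and
axis for pursuit — with CR1 cluster-robust standard errors by participant
and t tests on m−1 degrees of freedom (m = participants). Repeated trials
demand within-participant correlation handling; clustered OLS does that
without committing to a random-effects structure the source procedure
never specified. Interaction tests are Wald chi-square tests on the
cluster-robust covariance, with difference-in-differences pairwise
contrasts for two-level factors.

Bonferroni correction is applied only to the correlation family (the
number of metric × score pairs by default); group contrasts are reported
unadjusted. Impairment is strict: a score must lie *more than* 2 SD to the
worse side of the control mean, with the worse side declared per metric in
`metric_directions()` (higher-is-worse for counts and timings;
lower-is-worse for longest fixation, amplitude error and pursuit gain).
The ROC sweep evaluates every midpoint between adjacent unique scores plus
±∞ in both threshold directions and maximises accuracy; among equally
accurate cut-offs the more sensitive one wins (tie-break chosen here; the
procedure's own tie rule is unknown).

## The synthetic cohort model

The simulator generates what the analysis assumes: 250 Hz traces with the
exact task schedule (1+3 fixation trials; 4 blocks × 10 saccade trials
covering all 10 target locations per block with gap/overlap in an ABBA
design; 2+6 pursuit trials alternating axes). Fixation offset is fixed at
500 ms; target onset is 700 ms (gap) or 300 ms (overlap).

* **Saccade waveforms** have a raised-cosine velocity profile with peak
  velocity from the main sequence V = 500·scale·(1−e^(−A/14°)) °/s and
  duration D = 2A/V, so displacement integrates to A exactly. The
  main-sequence constants are literature-typical conventions, not
  estimates from any dataset. A consequence: amplitudes below ~1° peak
  under 35 °/s and sit at the parser's detection floor, so simulated SWJ
  amplitudes are drawn in [1.25°, 1.7°] (returns clamped to [1.05°, 1.9°])
  — small enough to be unambiguous SWJs, large enough to be detectable,
  and far enough from the strict 2° gate that measurement noise
  (SD ≈ 0.13°) rarely crosses it.
* **Noise** is band-limited: moving-average-filtered white noise (100 ms
  window) rescaled to SD 0.1°, i.e. drift-like fixational noise. White
  noise of that SD at 250 Hz would put ~18 °/s of noise on every velocity
  sample and make threshold parsing meaningless; real video-oculography
  noise is strongly band-limited. The resulting velocity noise is ~5 °/s
  per component.
* **Latencies** are log-normal (median per group, σ on the log scale, a
  participant-level median multiplier of e^(0.15z)), which produces the
  right-skew that makes the square-root transform meaningful; overlap
  trials add a fixed penalty. Main-saccade amplitude is gain ×
  eccentricity + N(0, 0.3°); corrective saccades close 90% of the residual
  error every ~150–280 ms until gaze is within 1.5° or the 5000 ms window
  ends. Wrong-direction first saccades (profile probability) leave the
  subsequent correctives starting far from centre, so those trials are
  removed by the main-saccade algorithm — the mechanism behind the higher
  removal rates of the impaired profiles.
* **Pursuit** integrates eye velocity = gain × target velocity between
  saccades; positional error > 1.5° sustained for 60 ms triggers a
  catch-up saccade closing 95% of it, and `catchup_rate` adds anticipatory
  jumps ~2.2–3.2° ahead of the target.
* **Reproducibility**: one root seed; per-participant sub-seeds drawn once
  up front, so cohorts are byte-identical across runs and participants are
  independent streams.

The default group profiles encode only the qualitative phenotype ordering
(PCA: slow, hypometric, overlap-sensitive, low gain; typical AD: frequent
SWJs, slightly elevated peak velocity, intermediate elsewhere; controls:
baseline) with group sizes 22/17/20 and the published age distributions.
No distributional forms or effect magnitudes for patient metrics are
available, so profile values are package choices; a green ordering test
establishes that the pipeline ranks the groups correctly on cohorts *built
to differ that way* — it is not evidence about real patients, effect
sizes, or the discriminative power of any metric in practice. Likewise the
simulator does not model vendor noise spectra, head motion, pupil
dynamics beyond binary validity, calibration error, or the unanalysed
jittering-target condition.

## Known limitations

* Detection equivalence with commercial parsers is at the level of event
  counts and timings on simulated data, not bit-for-bit event boundaries.
* Measured latencies carry a systematic parser delay of ~5–15 ms (time to
  cross the velocity threshold); contrasts (gap/overlap, group
  differences) are unaffected because the delay cancels.
* Whether trial-level or participant-mean values entered the original
  group models is unknown; trial-level clustered OLS is this package's
  documented choice, and `participant_summaries()` supports the other
  convention.
* The per-sample gain estimator is ratio-based by construction; its known
  turnaround pathology is mitigated, not removed, by the minimum
  target-speed guard.
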