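---
title: "Methods: synthetic gait cohorts and between-session reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic gait cohorts and between-session reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitrel)
```

## What the package computes

`gaitrel` quantifies how repeatable a gait-analysis system is between two
measurement days. The raw material is a set of walking passes, each a
synchronized recording of bilateral lower-limb joint angles (hip, knee,
ankle in the sagittal, frontal and transverse planes, degrees) and
landmark positions (heel, toe, sacrum; anterior-posterior, mediolateral
and vertical axes, meters) at a fixed sampling rate (60 Hz by default).
From these the pipeline produces three families of reliability indices:

1. **Full-curve RMSD.** Each subject-session's strides are
   ensemble-averaged into one 101-point gait-cycle curve per joint/plane;
   the root-mean-square difference between the two sessions' curves is
   averaged over subjects.
2. **SEM of discrete kinematic variables.** Windowed extrema, values at
   named cycle points, and ranges of motion (32 variables) are extracted
   per stride, averaged within subject-session, and summarized by the
   standard error of measurement.
3. **SEM and SEM% of spatiotemporal parameters.** Fifteen stride-level
   timing and distance parameters, with SEM% = 100·SEM/|grand mean|.

## Event detection and stride segmentation

Initial contact (IC) and toe-off (TO) are detected with the
coordinate-based method: in a progression-aligned frame, the heel is
furthest ahead of the sacrum exactly at IC, and the toe is furthest
behind the sacrum at TO, so IC is a local maximum of
`heel_AP - sacrum_AP` and TO a local minimum of `toe_AP - sacrum_AP`.
Two variants of this family exist (coordinate- and velocity-based); the
coordinate-based one is implemented because its extrema are directly
checkable against ground truth. Peaks closer together than 0.4 times the
median inter-peak interval are suppressed (larger magnitude wins, ties go
to the earlier index). The progression direction of a pass is taken from
the sign of the net sacrum displacement, which makes out-and-back
walkway protocols work without bookkeeping.

Strides are one IC-to-next-IC window of the analysis (dominant) side.
A window is kept only if it contains exactly one ipsilateral TO and one
contralateral IC and TO in the order `contra TO < contra IC < ipsi TO`.
Automated quality rules replace manual screening: a stride is dropped,
with a logged reason, if its duration deviates more than 40% from the
trial median or its stance fraction falls outside (0.4, 0.8).

Each retained stride is linearly interpolated onto 101 equally spaced
points (0-100% of the gait cycle). Sample indices are 0-based throughout
(`time = index / fs`).

Noisy recordings can be conditioned with a zero-lag low-pass Butterworth
filter (2nd order applied forward and backward, 6 Hz cutoff) before
detection; it is off by default because the synthetic signals are
noise-free and filtering would only blur the ground-truth comparison.

## Discrete variables and phase windows

Phase windows are derived per stride from its own event phases: stance
`[0, TO]`, swing `[TO, 1]`, stance halves split at mid-stance (`TO/2`),
double-support intervals DLS1 `[0, contra TO]` and DLS2
`[contra IC, TO]`, single support between them, and a stance-to-swing
transition window `[mid-stance, TO + 0.2·swing]` used for the ankle
plantarflexion peak, which sits at or just after toe-off. Mid-stance and
mid-swing are the midpoints of stance and swing. By construction
DLS1 + SLS + DLS2 = stance.

Reducers are deliberately simple: `max`/`min` over window samples
(inclusive bounds on the 1% phase grid), `value_at_point` at the nearest
grid sample (avoiding a second interpolation), and full-cycle
`range`. Extrema named for negative-direction motions (extension,
abduction, eversion, external rotation, plantarflexion) report the
*signed minimum* — an "extension maximum" of a knee that never leaves
flexion is still positive. One registry entry, the ankle frontal-plane
`MaxExt_Swing`, is terminologically odd but retained as reported in
published results tables; it is implemented as the signed swing minimum
(eversion-direction extremum) rather than silently renamed.

## Spatiotemporal parameters

Temporal parameters are event-index arithmetic: stride, stance, swing,
DLS1/DLS2/SLS and step times, plus cadence `120/stride_time` (steps per
minute under step symmetry — the analysis is single-sided). Swing and
single-support are computed as partition residuals so the identities
`stride = stance + swing` and `stance = DLS1 + SLS + DLS2` close
exactly. Spatial parameters come from the landmarks: stride length is
the heel's fore-aft advance between consecutive ICs; step length the
ipsi-minus-contra heel separation at ipsilateral IC; step width the
absolute mediolateral heel separation at the same instant (the
convention is stated because no standard definition exists). Gait speed
is measured from the *sacrum* displacement over the stride rather than
as stride_length/stride_time, so that speed and length are independent
measurements and their ratio is a useful internal diagnostic.
Leg-length-normalized variants divide by leg length and are reported as
dimensionless multiples of leg length (per second for speed), even
though such rows are sometimes printed with absolute units.

## Reliability statistics

The unit of analysis is the subject-session mean: per-stride values are
averaged within a session after matching stride counts between the two
sessions (each subject truncated to the earlier `min(n1, n2)` valid
strides — deterministic, seed-free). Subjects missing a variable in
either session are dropped for that variable only.

SEM is the square root of the error mean square of the two-way subjects
× sessions ANOVA with one observation per cell,

$$\mathrm{SEM} = \sqrt{MS_E}, \qquad
MS_E = \frac{\sum_{ij}(x_{ij}-\bar x_{i\cdot}-\bar x_{\cdot j}+\bar
x_{\cdot\cdot})^2}{(n-1)(k-1)},$$

which absorbs a uniform between-day shift into the session main effect:
a purely systematic offset yields SEM = 0. For two sessions this equals
`sd(d)/sqrt(2)` with `d` the per-subject difference; both forms are
implemented and asserted equal. The ICC-based form
`SD·sqrt(1-ICC(3,1))` is also provided, with the variance base matching
the ICC decomposition (`SD² = (MS_subject + (k-1)MS_E)/k`), under which
it equals the ANOVA SEM algebraically — it serves as an internal
consistency cross-check, not as the primary estimator, since the
literature describes both routes without fixing one. Error bands follow
the conventional interpretation for joint angles: below 2° good, 2-5°
acceptable, above 5° concerning. Report output rounds SEM to two
decimals and SEM% to one, matching how such tables are usually printed;
all internal computation keeps full precision.

## The synthetic cohort generator

No public raw data accompany this kind of between-day protocol, so the
package ships a generator whose defaults emulate the study conditions:
21 subjects × 2 sessions × 7 passes per task, 60 Hz, leg length 0.84 m,
two task presets (self-selected pace: speed 1.35 m/s, stride 1.43 m,
step width 0.19 m, stance fraction 0.667; fast pace: 1.95 m/s, 1.68 m,
0.22 m, 0.644). Strides per pass defaults to 4 — a typical clean-stride
yield for a 10 m walkway; within-session stride counts are rarely
reported, so this is an explicit guess.

Every scalar follows an additive Gaussian hierarchy
*subject → session → stride*. The session level is the injected
measurement error: each session of a subject receives an independent
`N(0, var_between_session)` offset, so the pipeline's SEM should
recover `sqrt(var_between_session)`. Default SDs were chosen once to
sit on published between-day scales: e.g. speed 0.26/0.07/0.035 m/s and
stride length 0.19/0.06/0.03 m at the subject/session/stride levels,
angle offsets 3°/1.5°/1°, angle excursion scale 5%/2%/1.2%. Speed and
length deviations are *coupled* (slope 0.55 m per m/s, residual keeping
the configured marginal SD) because faster walkers take longer strides;
independent draws would roughly double the spread of the derived stride
time relative to real cohorts. Stance fraction, contralateral offset
and step width vary at subject and session level but not stride to
stride, keeping landmark signals smooth within a pass. Truncated draws
(physical bounds, e.g. stance fraction in (0.42, 0.82)) use rejection
with at most 100 retries and then fail loudly rather than silently
distorting the distribution.

Joint-angle channels are truncated Fourier series (4 harmonics) per
joint/plane, with default coefficients fitted to periodic splines
through control points that reproduce textbook healthy-walking shapes
and published range-of-motion magnitudes (knee sagittal swing peak
~64° near 73% cycle, hip sagittal RoM ~46°, and so on). Per-stride
angle offset/scale draws are interpolated across stride midpoints so
the signal stays continuous at stride boundaries.

Landmarks are built to be kinematically consistent with the draws: the
sacrum advances at the drawn per-stride speed, the heel is
`sacrum + (L/4)·cos(2πφ)` in the progression-aligned frame (peaking
exactly at the ground-truth IC, advancing exactly the drawn stride
length per stride, and giving step length ≈ L/2 at a 50% contralateral
offset), and the toe trough sits exactly at the ground-truth TO.
Passes alternate walkway direction. The generator returns the full
ground truth (event times in continuous sample units; per-stride,
per-session and per-subject values), which the validation functions
(`event_detection_fidelity()`, `sem_recovery()`) consume.

All randomness flows from one seed through named streams (task,
subject, session, pass), so enlarging a cohort does not perturb
existing subjects, and identical configurations are bit-identical.

### What the generator does and does not emulate

It emulates the cohort structure, the variance hierarchy, realistic
stride timing/length scales, left-right phasing and steady-state
walking. It does *not* emulate pose-estimation noise structure
(autocorrelated marker jitter, segment-model errors), soft-tissue
artifact, turns or acceleration at walkway ends, or missing data.
Passing tests therefore demonstrate that the *pipeline and estimators*
are correct and unbiased under known conditions — not that any
particular capture system achieves a given error level on real data.

## Numerical choices

- Time normalization is plain linear interpolation with endpoints
  preserved exactly; 101 points so the phase grid is 1% steps.
- `value_at_point` uses the nearest grid sample rather than
  interpolating a second time.
- Partition identities are exact on integer event-sample counts and on
  `stride = stance + swing` (residual); the three-term support sum can
  differ from stance by one ulp of floating-point non-associativity,
  which tests treat as exact at tolerance 1e-15.
- A noise-free cohort gives exactly zero SEM and RMSD (both sessions
  are bitwise identical). Exactly zero *across-stride* variance
  additionally requires the stride period to be an integer number of
  samples (e.g. 1.1 s at 60 Hz); otherwise the sampling grid drifts
  across the cycle phase by design, as it does in real recordings.
- Event quantization at 60 Hz bounds per-event timing error at one
  sample (±17 ms) and stride-length error at roughly `2·speed/fs`;
  validation tolerances are derived from these bounds, not tuned.

## Problem sizes used in the shipped analyses

The analysis scripts and the acceptance script run the full study
geometry (21 subjects × 2 sessions × 7 passes × 4 strides per task,
~2 350 strides per task) for the pipeline results, 200 Monte-Carlo
cohorts per injected error SD for estimator recovery, and 20 noise-free
cohorts for detection fidelity; the unit-test suite uses smaller
cohorts (2-6 subjects) chosen so each property is still fully
exercised.

## Known limitations

- The generator's Gaussian hierarchy has no heavy tails, no outlier
  strides and no session-by-variable correlation beyond the
  speed-length coupling; SEM% for near-zero-mean variables is unstable
  by construction (reported as missing when the grand mean is zero).
- Only the coordinate-based event detector is implemented; the
  velocity-based variant would be a natural extension.
- C3D input is an optional adapter not available in this build; the
  CSV trial dialect is the interchange format.
- Minimal detectable change, Bland-Altman limits and curve-level
  statistical parametric mapping are out of scope.
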