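---
title: "Models and methods behind gaitcue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gaitcue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcue)
```

`gaitcue` implements, end to end, an on-demand gait-synchronous cueing
system for freezing of gait (FoG) driven by a single foot-mounted inertial
sensor, together with the synthetic data and the evaluation methodology
needed to study such a system on the desk. This vignette is the package's
account of its models: what is computed, under which assumptions, which
parameters matter, and what the synthetic experiments do and do not show.

## The signal model and the synthetic gait generator

A foot-mounted 6-axis IMU (200 Hz, ±16 g, ±2000 °/s) measures specific
force $f_b = R^\top(a_g - g)$ and body angular rate, where $R$ is the
sensor-to-global rotation and $g = (0,0,-9.80665)$ m/s². The generator
synthesises these signals *exactly* from a smooth foot trajectory, so every
downstream estimate has a known ground truth:

* **Swing trajectory.** Each stride is a swing of duration $T$ with
  minimum-jerk horizontal displacement $s(\tau) = L(10\tau^3 - 15\tau^4 +
  6\tau^5)$ along the heading (zero velocity and acceleration at both
  ends), a raised-cosine vertical lift, and the foot-pitch profile
  $\theta(\tau) \propto -\sin(2\pi\tau)(1-\cos 2\pi\tau)$, normalised so
  the `foot_lift_deg` parameter is the peak pitch magnitude. Pitch dips
  negative (toe-down) at toe-off and rises positive before heel strike —
  the shape a gait-phase detector must recognise. Yaw changes during pivot
  strides follow a minimum-jerk ramp, so turning truth is exact.
* **Heel strike.** A decaying 40 Hz vertical oscillation (≈ 60 ms, near-zero
  velocity integral) is appended after each swing. It reproduces the impact
  transient of real foot-worn recordings without biasing displacement.
* **FoG subtypes.** Shuffling: strides ≤ 0.25 m with < 5° foot lift.
  Festination: stride length shrinking geometrically (ratio 0.85) with a
  shortening cycle. Shank trembling: separated heel-lift bursts of 5 Hz
  pitch oscillation (0.35 s on, 0.45 s quiet) so each burst is an
  annotatable motion phase. Akinesia: rest-like signal inside a marked
  episode — by construction undetectable by a step-based system, which is
  why the rhythmic open-loop mode exists. Each FoG segment is covered by
  exactly one ground-truth episode.
* **Sit-to-stand / sitting (FAC protocol)** is modelled as postural sway:
  a yaw wobble with a whisper of pitch — rotational energy above rest but
  far below the motion thresholds, i.e. *unrest without motion phases*.
  Yaw wobble is used deliberately: a yaw rotation leaves the accelerometer
  reading unchanged, so sway cannot masquerade as tilt.
* **Noise.** Additive white Gaussian noise (defaults $\sigma_{acc} = 0.15$
  m/s², $\sigma_{gyr} = 1.5$ °/s) plus a constant per-trial gyro bias drawn
  from U(−0.5, 0.5) °/s — typical consumer-MEMS figures.

Defaults describe an unhurried Parkinsonian walker: stride 1.2 m, cadence
1 Hz (swing fraction 0.4), foot lift 20°. The default cohort
(`make_cohort()`, 20 subjects × ~60 s) draws stride length from
U(1.0, 1.4) m, cadence from U(0.8, 1.2) Hz and foot lift from U(15, 25)°
per subject, and each trial mixes straight walking with one segment each of
shuffling, trembling and festination plus a half turn (≈ 47 motion phases,
one third FoG-affected).

**What the generator does not emulate:** soft-tissue artefacts, sensor
mounting slip, magnetic disturbance (no magnetometer is modelled at all),
medication state, or the enormous within-patient variability of real FoG.
Passing the synthetic property suite therefore demonstrates internal
consistency of the pipeline — detectability of kinematically plausible
subtypes at realistic noise — not clinical performance. The two patients'
published numbers are *inputs* to the worked evaluation examples, never
reproduction targets.

## Orientation estimation

A causal complementary filter propagates z-y-x Euler angles by trapezoidal
gyro integration and pulls roll and pitch toward the accelerometer
inclination with gain 0.02 per sample (time constant ≈ 0.25 s at 200 Hz);
yaw is gyro-only and drifts slowly, which is why all turning features are
*per-phase relative* angles. Two numerical choices matter:

* The accelerometer correction is applied only in quasi-static moments,
  $|\,\lVert f_b\rVert - g\,| < 1.5$ m/s². Without this gate the large
  dynamic accelerations of a swing drag the pitch estimate tens of degrees
  off and motion phases never close.
* Initialization takes roll/pitch from the first accelerometer sample; an
  all-zero acceleration stream has no defined inclination and is rejected.

## Gait-phase detection

Three phases are distinguished causally, per sample: **rest** (both energy
signals low for ≥ 100 ms), **unrest** (anything above rest), and **motion**
(a sub-phase of unrest). The energy signals are the gyro norm and the
gravity-free acceleration norm, each smoothed with a causal 50 ms boxcar —
at the default noise level the raw 3-axis acceleration norm sits near the
closing threshold, so unsmoothed closure would chatter. A motion phase

* **opens** when the smoothed gyro norm exceeds 50 °/s *or* the pitch
  excursion from the last rest pitch exceeds 3° (toe-off proxy; the pitch
  path is what catches < 5° shuffling steps),
* **closes** when both signals stay below half their thresholds for 50 ms
  (heel-strike proxy). The recorded phase end is the energy-drop time; the
  end *event* is emitted 50 ms later when the dwell completes, so event
  emission is strictly causal and never precedes the true swing end,
* is **discarded** if shorter than 60 ms; start events are debounced by the
  same 60 ms so that batch and streaming outputs are identical.

A safety guard closes a phase and re-anchors the pitch baseline if both
energy signals stay below the *rest* thresholds for 0.5 s while the phase
is still open — without it, a corrupted rest-pitch reference (e.g. after
atypical postural activity) could hold a phase open indefinitely.

This configuration yields the delay signature expected of
threshold-crossing detectors: median start delay ≈ 50–65 ms (the minimum-jerk
swing accelerates slowly out of toe-off), median end delay ≈ 5–20 ms, and
detected durations slightly shorter than annotated ones. On the default
cohort the detection rate under the exclusive-overlap matching rule is
essentially 100%, comfortably above the 94% property the test suite
asserts; the margin is deliberate, since the synthetic signals lack the
adversarial artefacts of patient data.

## Per-phase features and stride estimation

Ten features are computed at the end of each motion phase, strictly from
samples up to the phase end: max acceleration norm, max/min pitch, stride
length, max stride velocity in the transverse (horizontal) plane, turning
angle, turned flag, max/mean turn rate, and stride duration. Velocity comes
from integrating the gravity-free global acceleration from the last rest
sample before the phase (zero-velocity anchor, ZUPT) and is linearly
de-trended so it returns to zero at the phase end — the standard pedestrian
dead-reckoning correction, which cancels any constant acceleration bias
exactly. Conventions the package fixes: pitch is toe-up positive; stride
length is the norm of the horizontal displacement over the phase (phase-only,
not rest-to-rest); the turned flag fires at |turning angle| > 22.5°, half a
45° pivot step. Phases without a zero-velocity anchor within 5 s are
integrated from their own start and flagged `degraded`.

On noise-free input the extractor recovers stride length within 0.1% and
turning angle within 0.3° when evaluated over the true swing interval. Over
*detected* phases the start-detection delay excludes the first ~2% of the
minimum-jerk displacement — an inherent property of causal detection, not of
the extractor, and the reason delay and recovery are reported separately.

## Classification

The motion-phase classifier is discrete (SAMME) AdaBoost with decision
trees of depth ≤ 3 as weak learners and ten boosting rounds — small enough
to run on a stimulator microcontroller and to serialize as plain JSON. The
weak learner is a weighted CART-style tree: exhaustive midpoint threshold
search, weighted Gini impurity, deterministic tie-breaks (lower feature
index, then smaller threshold), so training is bit-reproducible. The score
is the alpha-weighted vote share for `fog`, thresholded at 0.5; AUC is the
rank statistic of that score. Class weights are unbalanced by default, with
a config flag to equalize them. Leave-one-subject-out cross-validation
reports per-fold metrics as mean ± sd and a total from the summed confusion
matrix. On the default cohort, LOSO AUC saturates near 100% — the synthetic
subtypes are deliberately well-separated in stride length and foot lift —
while label permutation drops it to chance, which is the meaningful control
here.

## The cueing controller

Classification happens at motion-phase end, so on-demand cueing is an
event-driven state machine over `motion_start` / `motion_end` events whose
timestamps are shifted by the transport latency (7.5 ms default) and
quantized to the shared 1 ms clock:

* A FoG-classified `motion_end` at time $t$ presumes an episode until
  $t + t_{AGSC,on}$; later FoG phases extend the interval (never shorten
  it).
* During an active interval every `motion_start` opens a pulse train,
  unless it falls within $t_{off}$ of the previous train's end; the train
  ends at `motion_end`, clamped into $[t_{min}, t_{max}]$ = [0.2 s, 0.8 s]
  (0.2 s so cues are reliably perceived, 0.8 s as a safety cap above the
  longest plausible motion phase); a train still open at $t_{max}$ is
  force-closed.
* The phase that *opens* an interval can only be cued retroactively —
  onset-cueing of it is causally impossible — so it receives a $t_{min}$
  train at its classification instant. This behaviour is behind a flag
  (`cue_trigger_phase`), since an embedded implementation could equally
  choose to cue only subsequent phases.

$t_{AGSC,on}$ defaults to 5 s (a typical stride interval of ~1 s keeps an
ongoing episode covered) and $t_{off}$ to 0.1 s (below the shortest
plausible inter-phase gap); both are configuration, not constants. The
controller is verified train-for-train against an independent brute-force
simulator that walks an integer 1 ms timeline, over 1000 randomized event
streams. Rhythmic open-loop cueing — the fallback a patient triggers during
akinesia — emits periodic trains of `duty × period`, lengthened to
$t_{min}$ if needed, with $t_{off}$ always respected.

## Evaluation methodology

All interval logic is on half-open intervals $[start, end)$; a shared
endpoint is not an overlap, which prevents double matching at boundaries.

* **Matching:** a detected phase is *exclusive* to an annotated phase if it
  overlaps that one and no other. An annotated phase is correctly detected
  iff at least one exclusive detected phase overlaps it; among several, the
  earliest is the match and the rest are neglected. Detected phases with
  zero or two-plus annotated overlaps are false detections (counted once).
* **Delays:** start delay, end delay and duration difference per matched
  pair, summarized by medians and quartiles.
* **Coverage:** within the union of on-demand intervals, the stimulated
  share of motion-phase time and of non-motion-phase time, computed with
  exact interval arithmetic (tested against a 1 ms rasterization).
* **FoG truth:** a detected phase is FoG-associated iff its end time lies
  in an expert episode (inclusive start, exclusive end).
* **Reports:** counts of phases / FoG phases / cued phases and the
  cueing-active percentage; printed rates are rounded half-up to one
  decimal, reproducing the `283 (94.0 %)` reporting style, and per-subject
  cueing shares are averaged per course, then per subject, then overall.

## Problem sizes and reproducibility

Every stochastic step is seeded: scenarios own a seed, `make_cohort()`
derives per-trial seeds from one master seed, and the pipeline itself is
deterministic, so identical inputs give bitwise-identical outputs. The
standard experiment sizes — a 20-subject × 60 s cohort for detection and
LOSO properties, 1000 random event streams for the controller oracle, 300
random instances for the matching oracle — run in about a minute in total
and are the package's chosen balance between statistical comfort and a
test suite that stays pleasant to run.

## Known limitations

* Yaw is relative and drifts with gyro bias; absolute heading (and thus
  turn direction over long spans) is out of reach without a magnetometer,
  mirroring the limits of indoor foot-IMU systems.
* Akinesia is undetectable by construction for a step-triggered classifier;
  the rhythmic mode exists for exactly that case and is invoked
  programmatically, not by gesture recognition.
* The classifier's saturated synthetic performance says nothing about the
  separability of real patient features; the package's value there is the
  harness (features, LOSO, metrics), not the numbers.
* Roll is assumed small (flat-foot mounting); heavily inverted/everted foot
  placement would need a richer attitude parameterization.
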