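# gaitcue

Freezing of Gait (FoG) is one of the most disabling motor symptoms of
Parkinson's disease: episodic failures of stepping — shuffling, festination,
shank trembling, up to complete akinesia — that strike at turns and doorways
and cause falls. External cueing (here: sensory electrical pulse trains to
the peroneal nerve) can restore effective stepping, but continuous cueing
risks habituation. The alternative is *on-demand gait-synchronous cueing*:
detect each foot motion from a single foot-mounted inertial sensor, classify
it as normal or FoG-affected, and cue only while an episode is presumed —
phase-locked to the detected motions.

`gaitcue` is a desk-scale R implementation of that whole system for method
developers and movement-disorder researchers: a synthetic foot-IMU gait
generator with ground-truth annotations, the causal signal pipeline that
would run on the sensor and stimulator, and the evaluation methodology used
to judge such systems against expert video annotation.

## What is in the box

* **Synthetic gait** (`gait_scenario()`, `generate_gait()`,
  `protocol_10mwt()`, `protocol_fac()`, `make_cohort()`) — 200 Hz 6-axis
  streams (±16 g, ±2000 °/s) built from smooth per-swing foot trajectories
  (minimum-jerk displacement, raised-cosine pitch), with FoG subtypes and
  exact per-stride truth.
* **Orientation** (`estimate_orientation()`) — causal complementary filter:
  gyro-integrated attitude `q(t)`, accelerometer-corrected roll/pitch in
  quasi-static moments, gravity-free global acceleration `a_g(t)`.
* **Gait-phase detection** (`detect_phases()`, `stream_step()`) — causal
  rest / unrest / motion segmentation with hysteresis; the motion phase (MP)
  approximates the swing phase, and shuffles and trembling heel lifts count
  as MPs too. Batch and streaming modes are exactly equivalent.
* **Features** (`extract_features()`) — the ten per-MP features computed at
  MP end: max acceleration norm, max/min pitch, stride length and max stride
  velocity from ZUPT-anchored integration with linear drift correction,
  turning angle, turned flag, max/mean turn rate, stride duration.
* **Classifier** (`fog_train()`, `predict()`, `loso_cv()`) — discrete
  (SAMME) AdaBoost over decision trees of depth ≤ 3, ten estimators,
  JSON-serializable, with leave-one-subject-out validation.
* **Cueing controller** (`run_session()`, `on_event()`,
  `rhythmic_cueing()`) — the event-driven state machine: a FoG-classified MP
  presumes an episode for `t_AGSC,on` seconds; every MP inside the interval
  is cued with a pulse train clamped into `[t_min, t_max]` = [0.2 s, 0.8 s],
  with ≥ `t_off` between trains; plus open-loop rhythmic cueing as the
  akinesia fallback.
* **Evaluation** (`match_phases()`, `delay_stats()`, `cueing_coverage()`,
  `label_detected()`, `classification_metrics()`, `gait_report()`) —
  exclusive interval-overlap matching, start/end delay statistics, temporal
  cueing coverage, end-time FoG labelling and Table-style gait reports with
  half-up printed rounding.

## Worked example

Train a classifier on a small simulated cohort, then run the full pipeline
on a freezing assessment course (FAC) trial with FoG provoked at the turns:

```r
library(gaitcue)

cohort <- make_cohort(n_subjects = 4, seed = 2)
feats <- dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
  out <- extract_all(cohort$stream[[i]])
  dplyr::mutate(out$features,
    subject = cohort$subject[i],
    label = label_detected(out$phases$motion, cohort$truth[[i]]$fog_episodes))
}))
model <- fog_train(feats[, 3:12], feats$label, classifier_config())

scen <- protocol_fac(subject_params(), fog_density = 1, seed = 42)
sim  <- generate_gait(scen)
session <- run_pipeline(sim$stream, model)
session
#> <cueing_session> 48.9 s: 37 motion phases (13 fog), 25 pulse trains, 3 cueing intervals
gait_report(session)
#> # A tibble: 1 × 7
#>   duration_s cueing_s n_mps n_fog_mps n_cued_mps percent_fog percent_cueing_active
#>        <dbl>    <dbl> <int>     <int>      <int>       <dbl>                 <dbl>
#> 1       48.9     7.42    37        13         22        35.1                  15.2
```

Of the 37 motion phases the detector found, 13 were classified FoG-affected;
they opened three on-demand cueing intervals in which 22 phases were cued
for 7.4 s of stimulation in total. Evaluating detection against the
generator's annotation:

```r
m <- match_phases(sim$truth$motion_phases, session$phases)
m
#> <fog_match> 37 annotated: 37 (100.0%) detected, 0 (0.0%) missed, 0 false
delay_stats(m)$summary
#> # A tibble: 3 × 4
#>   measure            q25   median     q75
#> 1 start_delay    0.0500   0.0650   0.0650
#> 2 end_delay      0.00500  0.00500  0.0177
#> 3 duration_diff -0.0600  -0.0600  -0.0300
```

Start detection lags toe-off by ~50–65 ms while end detection is nearly
immediate, so detected phases are slightly shorter than annotated ones — the
characteristic delay signature of threshold-crossing gait-phase detectors.
`autoplot(session, episodes = sim$truth$fog_episodes)` draws the session
timeline (phases coloured by classification, cueing intervals, pulse
trains); `autoplot(sim$stream)` plots the raw signals.

A thin command-line front end over the same functions is installed at
`inst/scripts/gaitcue-cli.R` (verbs `simulate`, `detect`, `features`,
`train`, `run`, `evaluate`).

## Further reading

The methods vignette (`vignettes/gaitcue-methods.Rmd`) documents the signal
model, every tunable parameter with units and defaults, the design decisions
behind the detector and controller, and what the synthetic-data experiments
do and do not demonstrate about real patient data.
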