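#' Run the full detection-classification-cueing pipeline
#'
#' Causally composes the stages that run distributed on the sensor and the
#' stimulator: orientation estimation, gait-phase detection, per-phase
#' feature extraction at motion-phase end, normal-vs-FoG classification, and
#' the on-demand cueing controller. Classification events reach the
#' controller at the motion-end emission time (never before the detected
#' phase end) plus the configured transport latency. The pipeline is
#' deterministic: identical inputs produce identical outputs.
#'
#' @param stream an [imu_stream()].
#' @param model a trained `fog_adaboost` (or [constant_classifier()]).
#' @param config a [cueing_config()].
#' @param params a [gpd_params()].
#' @param stim a [stimulation_params()].
#' @return an object of class `cueing_session`: list with `duration_s`,
#'   `orientation`, `phase_sequence`, `phases` (detected motion phases with
#'   `class_label` and `score`), `features`, `events`, `trains`,
#'   `intervals`, `config`.
#' @export
run_pipeline <- function(stream, model, config = cueing_config(),
                         params = gpd_params(),
                         stim = stimulation_params()) {
  validate_imu_stream(stream)
  warmup_s <- params$smooth_window_s + params$dwell_rest_s
  duration_s <- if (nrow(stream) >= 2L) diff(range(stream$t)) else 0
  empty <- function() {
    structure(
      list(
        duration_s = duration_s, orientation = NULL, phase_sequence = NULL,
        phases = dplyr::mutate(motion_phases(source = "detected"), score = numeric()),
        features = extract_features(motion_phases(), NULL),
        events = tibble::tibble(
          kind = character(), time = numeric(), class_label = character()
        ),
        trains = tibble::tibble(
          start = numeric(), end = numeric(), trigger = character()
        ),
        intervals = tibble::tibble(start = numeric(), end = numeric()),
        config = config
      ),
      class = "cueing_session"
    )
  }
  if (duration_s < warmup_s) {
    warning("stream shorter than the detector warm-up; returning empty outputs")
    return(empty())
  }
  orient <- estimate_orientation(stream, gain = params$gain)
  ps <- detect_phases(stream, orient, params)
  feats <- extract_features(ps, orient)
  phases <- ps$motion
  if (nrow(feats) > 0L) {
    pred <- predict(model, feats)
    phases$class_label <- pred$label
    phases$score <- pred$score
  } else {
    phases$score <- numeric(0)
  }
  # classification is available at the motion_end emission instant
  events <- ps$events
  if (nrow(events) > 0L) {
    end_rows <- events$kind == "motion_end"
    events$class_label <- "none"
    if (any(end_rows)) {
      idx <- match(events$phase_start[end_rows], phases$start)
      events$class_label[end_rows] <- phases$class_label[idx]
    }
  } else {
    events$class_label <- character()
  }
  sess <- run_session(events, config, stim)
  structure(
    list(
      duration_s = duration_s, orientation = orient, phase_sequence = ps,
      phases = phases, features = feats, events = events,
      trains = sess$trains, intervals = sess$intervals, config = config
    ),
    class = "cueing_session"
  )
}

#' @export
print.cueing_session <- function(x, ...) {
  cat(sprintf(
    "<cueing_session> %.1f s: %d motion phases (%d fog), %d pulse trains, %d cueing intervals\n",
    x$duration_s, nrow(x$phases),
    if (nrow(x$phases)) sum(x$phases$class_label == "fog") else 0L,
    nrow(x$trains), nrow(x$intervals)
  ))
  invisible(x)
}
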