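#' Cueing controller parameters
#'
#' The on-demand gait-synchronous cueing controller is governed by four
#' durations: `t_agsc_on`, how long a FoG episode is presumed after a
#' FoG-classified motion phase ends; `t_off`, the minimum pause between pulse
#' trains; and `t_min`/`t_max`, the minimum and maximum pulse-train duration
#' (0.2 s so that cues are reliably perceived, 0.8 s as a safety cap just
#' above the longest plausible motion phase). `event_latency` models the
#' sensor-to-stimulator transport delay (7.5 ms by default; 0 disables it).
#'
#' @param t_agsc_on presumed-episode duration after a FoG phase, seconds.
#' @param t_off minimum gap between pulse trains, seconds.
#' @param t_min minimum pulse-train duration, seconds.
#' @param t_max maximum pulse-train duration, seconds.
#' @param event_latency event transport delay, seconds.
#' @param cue_trigger_phase should the FoG-classified phase that opens a
#'   cueing interval itself receive a `t_min` cue at its classification
#'   instant? Classification happens only at phase end, so cueing that first
#'   phase at its onset is causally impossible; this retroactive short cue is
#'   the closest realizable behaviour and can be disabled.
#' @return a list of class `cueing_config`.
#' @export
cueing_config <- function(t_agsc_on = 5, t_off = 0.1, t_min = 0.2,
                          t_max = 0.8, event_latency = 0.0075,
                          cue_trigger_phase = TRUE) {
  if (any(c(t_agsc_on, t_off, t_min, t_max) <= 0) || event_latency < 0) {
    stop_invalid("cueing_config durations must be positive")
  }
  if (t_min > t_max) {
    stop_invalid("cueing_config needs t_min <= t_max")
  }
  if (t_off >= t_agsc_on) {
    stop_invalid("cueing_config needs t_off < t_agsc_on")
  }
  structure(
    list(
      t_agsc_on = t_agsc_on, t_off = t_off, t_min = t_min, t_max = t_max,
      event_latency = event_latency,
      cue_trigger_phase = isTRUE(cue_trigger_phase)
    ),
    class = "cueing_config"
  )
}

#' Stimulation pulse parameters
#'
#' Pulse trains carry the electrical parameters of the biphasic stimulation:
#' channel (1-5), current amplitude (<= 100 mA), pulse width (30-1000 us) and
#' frequency (1-100 Hz). The default is the sensory-level setting used for
#' peroneal-nerve cueing (12 mA, 300 us, 35 Hz). Values outside the hardware
#' ranges are rejected.
#'
#' @param channel stimulation channel, integer 1..5.
#' @param amplitude_ma current amplitude in mA, at most 100.
#' @param pulse_width_us pulse width in microseconds, 30..1000.
#' @param frequency_hz pulse frequency in Hz, 1..100.
#' @return a list of class `stimulation_params`.
#' @export
stimulation_params <- function(channel = 1, amplitude_ma = 12,
                               pulse_width_us = 300, frequency_hz = 35) {
  if (!channel %in% 1:5) {
    stop_invalid("channel must be an integer in 1..5")
  }
  if (amplitude_ma <= 0 || amplitude_ma > 100) {
    stop_invalid("amplitude must be in (0, 100] mA")
  }
  if (pulse_width_us < 30 || pulse_width_us > 1000) {
    stop_invalid("pulse width must be in [30, 1000] us")
  }
  if (frequency_hz < 1 || frequency_hz > 100) {
    stop_invalid("frequency must be in [1, 100] Hz")
  }
  structure(
    list(
      channel = as.integer(channel), amplitude_ma = amplitude_ma,
      pulse_width_us = pulse_width_us, frequency_hz = frequency_hz
    ),
    class = "stimulation_params"
  )
}

#' Classifier hyper-parameters
#'
#' The motion-phase classifier is an AdaBoost ensemble of shallow decision
#' trees: ten estimators of depth at most three, thresholding the FoG vote
#' share at 0.5 by default.
#'
#' @param n_estimators number of boosting rounds (weak learners).
#' @param max_tree_depth maximum depth of each decision tree.
#' @param seed integer seed for any randomized step.
#' @param decision_threshold FoG vote share above which a phase is labelled
#'   `fog`.
#' @param balance_classes if `TRUE`, initial sample weights are scaled so
#'   both classes carry equal total weight.
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(n_estimators = 10, max_tree_depth = 3,
                              seed = 1L, decision_threshold = 0.5,
                              balance_classes = FALSE) {
  if (n_estimators < 1 || max_tree_depth < 1) {
    stop_invalid("n_estimators and max_tree_depth must be >= 1")
  }
  if (decision_threshold < 0 || decision_threshold > 1) {
    stop_invalid("decision_threshold must be in [0, 1]")
  }
  structure(
    list(
      n_estimators = as.integer(n_estimators),
      max_tree_depth = as.integer(max_tree_depth),
      seed = as.integer(seed),
      decision_threshold = decision_threshold,
      balance_classes = isTRUE(balance_classes)
    ),
    class = "classifier_config"
  )
}

#' Read and write configuration objects as JSON
#'
#' @param x a `cueing_config`, `stimulation_params` or `classifier_config`.
#' @param path file path.
#' @return `read_config()` returns the reconstructed object.
#' @export
write_config <- function(x, path) {
  doc <- list(
    schema = "gaitcue/config/1", type = class(x)[1], values = unclass(x)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$schema, "gaitcue/config/1")) {
    stop_invalid("unrecognized config schema in ", path)
  }
  fn <- switch(doc$type,
    cueing_config = cueing_config,
    stimulation_params = stimulation_params,
    classifier_config = classifier_config,
    stop_invalid("unknown config type: ", doc$type)
  )
  do.call(fn, doc$values)
}
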