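# On-demand gait-synchronous cueing controller.
#
# Event-driven state machine: a FoG-classified motion phase opens (or
# extends) an on-demand cueing interval of length t_agsc_on; while an
# interval is active every motion phase is cued with a stimulation pulse
# train that starts at the motion-start event and ends at the motion-end
# event, clamped into [t_min, t_max], with at least t_off between
# consecutive trains. The FoG-classified phase that opens an interval can
# itself only be cued retroactively (classification happens at phase end),
# with a t_min train at its classification instant. Event times are
# quantized to the 1 ms controller clock after an optional transport
# latency shift.

EPS_T <- 1e-9

#' Initial controller state
#'
#' @return a list of class `cueing_state`.
#' @export
cueing_state <- function() {
  structure(
    list(
      interval_end = -Inf, # end of the active on-demand interval
      last_train_end = -Inf,
      open_start = NA_real_, # start of the currently open train
      cur_phase_cued = FALSE,
      last_time = -Inf,
      trains = list(), intervals = list()
    ),
    class = "cueing_state"
  )
}

emit_train <- function(state, start, end) {
  state$trains[[length(state$trains) + 1L]] <- c(start = start, end = end)
  state$last_train_end <- end
  state
}

extend_interval <- function(state, t, config) {
  new_end <- t + config$t_agsc_on
  if (t < state$interval_end - EPS_T) {
    # still inside the current interval: extend it (never shorten)
    k <- length(state$intervals)
    state$intervals[[k]]["end"] <- max(state$intervals[[k]]["end"], new_end)
  } else {
    state$intervals[[length(state$intervals) + 1L]] <-
      c(start = t, end = new_end)
  }
  state$interval_end <- max(state$interval_end, new_end)
  state
}

#' Feed one motion event to the cueing controller
#'
#' `event` is a list with `kind` (`"motion_start"` or `"motion_end"`),
#' `time` (seconds, already on the controller clock) and, for end events,
#' `class_label` (`"normal"`, `"fog"` or `"none"`). Events must be
#' time-ordered.
#'
#' @param state a [cueing_state()].
#' @param event the event.
#' @param config a [cueing_config()].
#' @return the updated state; completed pulse trains accumulate in
#'   `state$trains`.
#' @export
on_event <- function(state, event, config) {
  t <- event$time
  if (t < state$last_time - EPS_T) {
    stop_invalid("non-monotone event at t = ", t)
  }
  state$last_time <- t
  if (event$kind == "motion_start") {
    state$cur_phase_cued <- FALSE
    if (t < state$interval_end - EPS_T &&
      t >= state$last_train_end + config$t_off - EPS_T) {
      state$open_start <- t
      state$cur_phase_cued <- TRUE
    }
  } else if (event$kind == "motion_end") {
    if (!is.na(state$open_start)) {
      end <- min(
        max(state$open_start + config$t_min, t),
        state$open_start + config$t_max
      )
      state <- emit_train(state, state$open_start, end)
      state$open_start <- NA_real_
    }
    if (identical(event$class_label, "fog")) {
      state <- extend_interval(state, t, config)
      if (config$cue_trigger_phase && !state$cur_phase_cued &&
        t >= state$last_train_end + config$t_off - EPS_T) {
        state <- emit_train(state, t, t + config$t_min)
        state$cur_phase_cued <- TRUE
      }
    }
  } else {
    stop_invalid("unknown event kind: ", event$kind)
  }
  state
}

#' Run a cueing session over a list of motion events
#'
#' Shifts event times by the configured transport latency, quantizes them to
#' the 1 ms controller clock, folds [on_event()] over them, and returns the
#' completed pulse trains together with the on-demand cueing intervals.
#'
#' @param events tibble with columns `kind`, `time` and `class_label`
#'   (`class_label` is only read on `motion_end` events).
#' @param config a [cueing_config()].
#' @param params a [stimulation_params()] attached to every train.
#' @return list with `trains` (tibble `start`, `end`, `trigger`) and
#'   `intervals` (tibble `start`, `end`).
#' @export
run_session <- function(events, config = cueing_config(),
                        params = stimulation_params()) {
  events <- tibble::as_tibble(events)
  state <- cueing_state()
  if (nrow(events) > 0L) {
    if (!"class_label" %in% names(events)) {
      events$class_label <- "none"
    }
    times <- quantize_time(events$time + config$event_latency)
    o <- order(times, match(events$kind, c("motion_end", "motion_start")))
    for (i in o) {
      state <- on_event(
        state,
        list(
          kind = events$kind[i], time = times[i],
          class_label = events$class_label[i]
        ),
        config
      )
    }
    # a train still open when the event stream ends is force-closed at t_max
    if (!is.na(state$open_start)) {
      state <- emit_train(
        state, state$open_start, state$open_start + config$t_max
      )
    }
  }
  trains <- if (length(state$trains) > 0L) {
    tibble::tibble(
      start = vapply(state$trains, `[[`, 0, "start"),
      end = vapply(state$trains, `[[`, 0, "end"),
      trigger = "on_demand"
    )
  } else {
    tibble::tibble(start = numeric(), end = numeric(), trigger = character())
  }
  intervals <- if (length(state$intervals) > 0L) {
    tibble::tibble(
      start = vapply(state$intervals, `[[`, 0, "start"),
      end = vapply(state$intervals, `[[`, 0, "end")
    )
  } else {
    tibble::tibble(start = numeric(), end = numeric())
  }
  list(trains = trains, intervals = intervals, params = params)
}

#' Open-loop rhythmic cueing
#'
#' The fallback mode for akinetic episodes: periodic pulse trains of
#' duration `duty * period` from `start` until `stop`. Trains shorter than
#' `t_min` are lengthened to `t_min` with a warning; the `t_off` pause
#' between trains is always respected.
#'
#' @param start,stop window bounds in seconds (`stop <= start` yields an
#'   empty schedule).
#' @param period cueing period, seconds.
#' @param duty fraction of the period that is stimulated, in (0, 1).
#' @param params a [stimulation_params()].
#' @param config a [cueing_config()] supplying `t_min` and `t_off`.
#' @return tibble of pulse trains (`start`, `end`, `trigger = "rhythmic"`).
#' @export
rhythmic_cueing <- function(start, stop, period, duty,
                            params = stimulation_params(),
                            config = cueing_config()) {
  if (period <= 0 || duty <= 0 || duty >= 1) {
    stop_invalid("need period > 0 and duty in (0, 1)")
  }
  if (stop <= start) {
    return(tibble::tibble(
      start = numeric(), end = numeric(), trigger = character()
    ))
  }
  dur <- duty * period
  if (dur < config$t_min) {
    warning(
      "duty * period below t_min; trains lengthened to ", config$t_min, " s"
    )
    dur <- config$t_min
  }
  if (period - dur < config$t_off) {
    stop_invalid("period leaves less than t_off between trains")
  }
  starts <- seq(start, stop - dur + EPS_T, by = period)
  starts <- starts[starts + dur <= stop + EPS_T]
  tibble::tibble(
    start = starts, end = starts + dur, trigger = "rhythmic"
  )
}
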