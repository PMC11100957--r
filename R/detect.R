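# Causal rest / unrest / motion segmentation.
#
# The detector works on three derived signals: the (boxcar-smoothed) gyro
# norm, the smoothed gravity-free acceleration norm, and the estimated pitch
# relative to its value at the last rest. Rest requires both energy signals
# to stay low for a dwell time; motion opens when the gyro norm or the pitch
# excursion crosses its threshold (a toe-off proxy) and closes when both stay
# below half their thresholds for a closing dwell (a heel-strike proxy).
# Motion is a sub-phase of unrest; short blips under the minimum motion
# duration are debounced away. The same per-sample transition function
# drives both the batch and the streaming interface, so the two are exactly
# equivalent.

#' Gait-phase detector parameters
#'
#' Thresholds are chosen to catch small shuffling steps and trembling heel
#' lifts while rejecting sensor noise: rest requires gyro norm below
#' `rest_gyr_dps` and dynamic acceleration below `rest_acc_ms2` sustained for
#' `dwell_rest_s`; motion opens above `motion_gyr_dps` or a pitch excursion
#' beyond `motion_pitch_deg` away from the rest pitch, and closes when both
#' stay below half their thresholds for `dwell_close_s`.
#'
#' @param gain complementary-filter gain used when the caller lets
#'   [detect_phases()] estimate orientation itself.
#' @param rest_gyr_dps rest threshold on the smoothed gyro norm, deg/s.
#' @param rest_acc_ms2 rest threshold on the smoothed dynamic-acceleration
#'   norm, m/s^2.
#' @param dwell_rest_s dwell time for entering rest, seconds.
#' @param motion_gyr_dps motion-opening threshold on the gyro norm, deg/s.
#' @param motion_pitch_deg motion-opening threshold on the pitch excursion
#'   from rest, degrees.
#' @param close_frac fraction of the opening thresholds used for closing.
#' @param dwell_close_s dwell time for closing a motion phase, seconds.
#' @param min_motion_s minimum duration of a reported motion phase, seconds.
#' @param smooth_window_s causal boxcar window for the energy signals,
#'   seconds.
#' @param rebase_quiet_s safety horizon: if both energy signals stay below
#'   the rest thresholds this long while a motion phase is still open (a
#'   sign that the rest-pitch reference has drifted), the phase is closed at
#'   the start of the quiet run and the pitch baseline re-anchored.
#' @return a list of class `gpd_params`.
#' @export
gpd_params <- function(gain = 0.02, rest_gyr_dps = 10, rest_acc_ms2 = 0.6,
                       dwell_rest_s = 0.1, motion_gyr_dps = 50,
                       motion_pitch_deg = 3, close_frac = 0.5,
                       dwell_close_s = 0.05, min_motion_s = 0.06,
                       smooth_window_s = 0.05, rebase_quiet_s = 0.5) {
  vals <- c(
    rest_gyr_dps, rest_acc_ms2, dwell_rest_s, motion_gyr_dps,
    motion_pitch_deg, close_frac, dwell_close_s, min_motion_s,
    smooth_window_s, rebase_quiet_s
  )
  if (any(vals <= 0)) {
    stop_invalid("gait-phase detector thresholds must be positive")
  }
  structure(
    list(
      gain = gain, rest_gyr_dps = rest_gyr_dps, rest_acc_ms2 = rest_acc_ms2,
      dwell_rest_s = dwell_rest_s, motion_gyr_dps = motion_gyr_dps,
      motion_pitch_deg = motion_pitch_deg, close_frac = close_frac,
      dwell_close_s = dwell_close_s, min_motion_s = min_motion_s,
      smooth_window_s = smooth_window_s, rebase_quiet_s = rebase_quiet_s
    ),
    class = "gpd_params"
  )
}

det_state_new <- function(params, sample_rate_hz = 200) {
  w <- max(1L, round(params$smooth_window_s * sample_rate_hz))
  list(
    p = params, fs = sample_rate_hz,
    w = w, gbuf = numeric(w), abuf = numeric(w), nbuf = 0L, ibuf = 0L,
    dwell_rest_n = max(1L, round(params$dwell_rest_s * sample_rate_hz)),
    dwell_close_n = max(1L, round(params$dwell_close_s * sample_rate_hz)),
    rebase_n = max(1L, round(params$rebase_quiet_s * sample_rate_hz)),
    quiet_run = 0L, resting = FALSE, rest_pitch = NA_real_,
    in_motion = FALSE, open_t = NA_real_, open_i = NA_integer_,
    started = FALSE, close_run = 0L, drop_t = NA_real_, drop_i = NA_integer_,
    equiet_run = 0L, equiet_t = NA_real_, equiet_i = NA_integer_,
    i = 0L,
    phases = list(), events = list(), discarded = list()
  )
}

# One detector update on the derived signals. Returns the updated state;
# the per-sample label of the *current* sample is in st$label.
det_step <- function(st, t, gnorm, adyn, pitch) {
  p <- st$p
  st$i <- st$i + 1L
  st$ibuf <- st$ibuf %% st$w + 1L
  st$gbuf[st$ibuf] <- gnorm
  st$abuf[st$ibuf] <- adyn
  st$nbuf <- min(st$nbuf + 1L, st$w)
  # boxcar over the filled part of the ring buffer (unfilled slots are 0)
  sg <- sum(st$gbuf) / st$nbuf
  sa <- sum(st$abuf) / st$nbuf
  if (is.na(st$rest_pitch)) {
    st$rest_pitch <- pitch
  }
  if (!st$in_motion) {
    quiet <- (sg < p$rest_gyr_dps) && (sa < p$rest_acc_ms2)
    st$quiet_run <- if (quiet) st$quiet_run + 1L else 0L
    st$resting <- st$quiet_run >= st$dwell_rest_n
    if (st$resting) {
      st$rest_pitch <- pitch
    }
    open <- (sg > p$motion_gyr_dps) ||
      (abs(pitch - st$rest_pitch) > p$motion_pitch_deg)
    if (open) {
      st$in_motion <- TRUE
      st$open_t <- t
      st$open_i <- st$i
      st$started <- FALSE
      st$close_run <- 0L
      st$equiet_run <- 0L
      st$quiet_run <- 0L
      st$resting <- FALSE
      st$label <- "motion"
    } else {
      st$label <- if (st$resting) "rest" else "unrest"
    }
  } else {
    st$label <- "motion"
    closing <- (sg < p$close_frac * p$motion_gyr_dps) &&
      (abs(pitch - st$rest_pitch) < p$close_frac * p$motion_pitch_deg)
    if (closing) {
      if (st$close_run == 0L) {
        st$drop_t <- t
        st$drop_i <- st$i
      }
      st$close_run <- st$close_run + 1L
    } else {
      st$close_run <- 0L
    }
    if (!st$started && st$close_run == 0L &&
      (t - st$open_t) >= p$min_motion_s - 1e-9) {
      st$started <- TRUE
      st$events[[length(st$events) + 1L]] <- list(
        kind = "motion_start", time = t, phase_start = st$open_t,
        phase_end = NA_real_
      )
    }
    # safety guard: sustained energy-quiet with the phase still open means
    # the pitch baseline has drifted -- close at the quiet start and
    # re-anchor the rest pitch
    equiet <- (sg < p$rest_gyr_dps) && (sa < p$rest_acc_ms2)
    if (equiet) {
      if (st$equiet_run == 0L) {
        st$equiet_t <- t
        st$equiet_i <- st$i
      }
      st$equiet_run <- st$equiet_run + 1L
    } else {
      st$equiet_run <- 0L
    }
    if (st$close_run >= st$dwell_close_n) {
      st <- det_close(st, t, st$drop_t, st$drop_i)
    } else if (st$equiet_run >= st$rebase_n) {
      quiet_sofar <- st$equiet_run
      st$rest_pitch <- pitch
      st <- det_close(st, t, st$equiet_t, st$equiet_i)
      st$quiet_run <- quiet_sofar
    }
  }
  st
}

det_close <- function(st, t, drop_t, drop_i) {
  if (st$started) {
    st$phases[[length(st$phases) + 1L]] <- list(
      start = st$open_t, end = drop_t,
      start_i = st$open_i, end_i = drop_i, confirm = t
    )
    st$events[[length(st$events) + 1L]] <- list(
      kind = "motion_end", time = t, phase_start = st$open_t,
      phase_end = drop_t
    )
  } else {
    st$discarded[[length(st$discarded) + 1L]] <- c(st$open_i, st$i)
  }
  st$in_motion <- FALSE
  st$close_run <- 0L
  st$equiet_run <- 0L
  st$quiet_run <- 0L
  st$resting <- FALSE
  st
}

#' Segment a stream into rest, unrest and motion phases
#'
#' Applies the causal gait-phase detector to a stream and its orientation
#' estimate. The returned object carries per-sample labels, the maximal
#' rest/unrest/motion intervals, the detected motion phases and the
#' start/end events with their emission times (start events are debounced by
#' the minimum motion duration; end events are emitted when the closing
#' dwell completes, time-stamped with the emission time while the phase
#' record keeps the earlier energy-drop time as its end).
#'
#' @param stream an [imu_stream()].
#' @param orient a `fog_orientation` from [estimate_orientation()]; computed
#'   internally when `NULL`.
#' @param params a [gpd_params()] object.
#' @return a list of class `phase_sequence` with elements `samples`
#'   (tibble `t`, `label`), `phases` (maximal runs), `motion` (detected
#'   [motion_phases()]), and `events`.
#' @export
detect_phases <- function(stream, orient = NULL, params = gpd_params()) {
  validate_imu_stream(stream)
  if (!inherits(params, "gpd_params")) {
    stop_invalid("params must be created with gpd_params()")
  }
  if (is.null(orient)) {
    orient <- estimate_orientation(stream, gain = params$gain)
  }
  if (nrow(orient) != nrow(stream)) {
    stop_invalid("stream and orientation are not aligned")
  }
  n <- nrow(stream)
  gnorm <- sqrt(stream$gx^2 + stream$gy^2 + stream$gz^2)
  adyn <- sqrt(orient$agx^2 + orient$agy^2 + orient$agz^2)
  st <- det_state_new(params, imu_meta(stream)$sample_rate_hz)
  labels <- character(n)
  for (i in seq_len(n)) {
    st <- det_step(st, stream$t[i], gnorm[i], adyn[i], orient$pitch[i])
    labels[i] <- st$label
  }
  finalize_phase_sequence(st, stream$t, labels)
}

finalize_phase_sequence <- function(st, t, labels) {
  n <- length(t)
  # motion samples are exactly those inside kept phases [open, drop)
  if (n > 0L) {
    labels[labels == "motion"] <- "unrest"
    for (ph in st$phases) {
      labels[ph$start_i:max(ph$start_i, ph$end_i - 1L)] <- "motion"
    }
  }
  phases_tbl <- if (length(st$phases) > 0L) {
    tibble::tibble(
      start = vapply(st$phases, `[[`, 0, "start"),
      end = vapply(st$phases, `[[`, 0, "end"),
      confirm = vapply(st$phases, `[[`, 0, "confirm")
    )
  } else {
    tibble::tibble(start = numeric(), end = numeric(), confirm = numeric())
  }
  mp <- motion_phases(
    phases_tbl$start, phases_tbl$end,
    source = "detected"
  )
  runs <- if (n > 0L) {
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    dt <- if (n >= 2L) t[2] - t[1] else 0
    tibble::tibble(
      start = t[starts],
      end = c(t[utils::tail(starts, -1L)], t[n] + dt),
      phase = r$values
    )
  } else {
    tibble::tibble(start = numeric(), end = numeric(), phase = character())
  }
  events_tbl <- if (length(st$events) > 0L) {
    tibble::tibble(
      kind = vapply(st$events, `[[`, "", "kind"),
      time = vapply(st$events, `[[`, 0, "time"),
      phase_start = vapply(st$events, `[[`, 0, "phase_start"),
      phase_end = vapply(st$events, `[[`, 0, "phase_end")
    )
  } else {
    tibble::tibble(
      kind = character(), time = numeric(),
      phase_start = numeric(), phase_end = numeric()
    )
  }
  structure(
    list(
      samples = tibble::tibble(t = t, label = labels),
      phases = runs,
      motion = dplyr::bind_cols(mp, confirm = phases_tbl$confirm),
      events = events_tbl
    ),
    class = "phase_sequence"
  )
}

#' @export
print.phase_sequence <- function(x, ...) {
  cat(sprintf(
    "<phase_sequence> %d samples, %d motion phases\n",
    nrow(x$samples), nrow(x$motion)
  ))
  invisible(x)
}

#' Streaming gait-phase detection
#'
#' `stream_detector()` creates the online state; `stream_step()` consumes one
#' sample (a list or one-row data frame with `t, ax, ay, az, gx, gy, gz`) and
#' returns the updated state plus any `motion_start` / `motion_end` events
#' emitted at this sample. The streaming path shares its per-sample
#' arithmetic with [detect_phases()], so replaying a stream through
#' `stream_step()` yields exactly the batch phase sequence
#' (via `stream_result()`).
#'
#' @param params a [gpd_params()].
#' @param sample_rate_hz sampling rate of the incoming stream.
#' @return `stream_detector()` returns a state object; `stream_step()`
#'   returns `list(state, events)`; `stream_result()` returns the
#'   accumulated `phase_sequence`.
#' @export
stream_detector <- function(params = gpd_params(), sample_rate_hz = 200) {
  list(
    orient = orient_state_new(params$gain, sample_rate_hz),
    det = det_state_new(params, sample_rate_hz),
    last_t = -Inf, t = numeric(), labels = character()
  )
}

#' @rdname stream_detector
#' @param state a streaming state.
#' @param sample one sample with fields `t, ax, ay, az, gx, gy, gz`.
#' @export
stream_step <- function(state, sample) {
  t <- sample$t
  if (t <= state$last_t) {
    stop_invalid("out-of-order sample at t = ", t)
  }
  state$last_t <- t
  n_before <- length(state$det$events)
  res <- orient_step(
    state$orient,
    c(sample$ax, sample$ay, sample$az),
    c(sample$gx, sample$gy, sample$gz)
  )
  state$orient <- res$state
  pitch <- res$out[2]
  adyn <- sqrt(sum(res$out[8:10]^2))
  gnorm <- sqrt(sample$gx^2 + sample$gy^2 + sample$gz^2)
  state$det <- det_step(state$det, t, gnorm, adyn, pitch)
  state$t <- c(state$t, t)
  state$labels <- c(state$labels, state$det$label)
  new_events <- state$det$events[
    seq_len(length(state$det$events)) > n_before
  ]
  list(state = state, events = new_events)
}

#' @rdname stream_detector
#' @export
stream_result <- function(state) {
  finalize_phase_sequence(state$det, state$t, state$labels)
}
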