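# Per-motion-phase feature extraction.
#
# The ten features computed at the end of every detected motion phase:
# max. acceleration norm, max. pitch, min. pitch, stride length, max. stride
# velocity (transverse plane), turning angle, turned flag, max. turn rate,
# mean turn rate, stride duration. Velocity comes from integrating the
# gravity-free global acceleration from the last rest sample before the
# phase (zero-velocity update), linearly de-trended so that velocity returns
# to zero at the phase end; stride length is the norm of the horizontal
# displacement accumulated over the phase. Everything is computed strictly
# from samples at or before the phase end.

#' @keywords internal
feature_names <- function() {
  c(
    "max_acc_norm", "max_pitch", "min_pitch", "stride_length",
    "max_stride_velocity", "turning_angle", "turned_flag",
    "max_turn_rate", "mean_turn_rate", "stride_duration"
  )
}

#' Extract gait features for motion phases
#'
#' @param phases a `phase_sequence` from [detect_phases()], or a tibble of
#'   motion phases (`start`, `end`) to evaluate against the stream; phases
#'   must be time-ordered and non-overlapping.
#' @param orient a `fog_orientation` from [estimate_orientation()].
#' @param turn_threshold_deg absolute turning angle above which the turned
#'   flag is set (half of a 45 degree pivot step by default).
#' @param zupt_horizon_s how far back (seconds) to look for a zero-velocity
#'   anchor; without one within the horizon the phase is integrated from its
#'   own start and flagged `degraded`.
#' @return a tibble with one row per motion phase: `start`, `end`, the ten
#'   features in canonical order, and `degraded`.
#' @export
extract_features <- function(phases, orient, turn_threshold_deg = 22.5,
                             zupt_horizon_s = 5) {
  if (inherits(phases, "phase_sequence")) {
    labels <- phases$samples$label
    mp <- phases$motion
  } else {
    mp <- phases
    labels <- NULL
  }
  empty <- tibble::tibble(
    start = numeric(), end = numeric(),
    !!!stats::setNames(
      rep(list(numeric()), 10), feature_names()
    ),
    degraded = logical()
  )
  if (nrow(mp) == 0L) {
    return(empty)
  }
  if (is.unsorted(mp$start, strictly = FALSE) ||
    any(mp$start[-1] < mp$end[-nrow(mp)])) {
    stop_invalid("motion phases must be time-ordered and non-overlapping")
  }
  t <- orient$t
  dt <- stats::median(diff(t))
  if (is.null(labels)) {
    labels <- rep("rest", length(t)) # trusted caller-supplied phases
  }
  rows <- vector("list", nrow(mp))
  for (k in seq_len(nrow(mp))) {
    rows[[k]] <- extract_one(
      mp$start[k], mp$end[k], orient, labels, dt,
      turn_threshold_deg, zupt_horizon_s
    )
  }
  dplyr::bind_rows(rows)
}

extract_one <- function(p_start, p_end, orient, labels, dt,
                        turn_threshold_deg, zupt_horizon_s) {
  t <- orient$t
  i_start <- which(t >= p_start - 1e-9)[1]
  i_end <- max(which(t <= p_end + 1e-9))
  if (is.na(i_start) || i_start > i_end) {
    stop_invalid("motion phase lies outside the stream")
  }
  # zero-velocity anchor: last rest sample before the phase start
  anchor_candidates <- which(
    labels == "rest" & t < p_start & t >= p_start - zupt_horizon_s
  )
  degraded <- length(anchor_candidates) == 0L
  i_anchor <- if (degraded) i_start else max(anchor_candidates)

  idx <- i_anchor:i_end
  acc <- cbind(orient$agx[idx], orient$agy[idx], orient$agz[idx])
  tt <- t[idx]
  # cumulative trapezoid: v(anchor) = 0
  v <- apply(acc, 2, function(a) {
    c(0, cumsum((a[-1] + a[-length(a)]) / 2 * diff(tt)))
  })
  # linear de-trend so velocity returns to zero at phase end (ZUPT pair)
  span <- tt[length(tt)] - tt[1]
  if (span > 0) {
    ramp <- (tt - tt[1]) / span
    v <- v - outer(ramp, v[nrow(v), ])
  }
  # displacement over the phase only
  in_phase <- which(tt >= p_start - 1e-9)
  vp <- v[in_phase, , drop = FALSE]
  tp <- tt[in_phase]
  disp <- if (length(tp) >= 2L) {
    colSums((vp[-1, , drop = FALSE] + vp[-nrow(vp), , drop = FALSE]) / 2 *
      diff(tp))
  } else {
    c(0, 0, 0)
  }
  pitch <- orient$pitch[i_start:i_end]
  yaw_rate <- abs(orient$ggz[i_start:i_end])
  turning <- orient$yaw[i_end] - orient$yaw[i_start]
  tibble::tibble(
    start = p_start, end = p_end,
    max_acc_norm = max(sqrt(rowSums(
      cbind(
        orient$agx[i_start:i_end], orient$agy[i_start:i_end],
        orient$agz[i_start:i_end]
      )^2
    ))),
    max_pitch = max(pitch),
    min_pitch = min(pitch),
    stride_length = sqrt(disp[1]^2 + disp[2]^2),
    max_stride_velocity = max(sqrt(vp[, 1]^2 + vp[, 2]^2)),
    turning_angle = turning,
    turned_flag = as.numeric(abs(turning) > turn_threshold_deg),
    max_turn_rate = max(yaw_rate),
    mean_turn_rate = mean(yaw_rate),
    stride_duration = p_end - p_start,
    degraded = degraded
  )
}

#' @rdname extract_features
#' @param stream an [imu_stream()]; convenience wrapper that estimates
#'   orientation, detects phases and extracts their features in one call.
#' @param params a [gpd_params()].
#' @export
extract_all <- function(stream, params = gpd_params(), ...) {
  orient <- estimate_orientation(stream, gain = params$gain)
  ps <- detect_phases(stream, orient, params)
  list(
    orientation = orient, phases = ps,
    features = extract_features(ps, orient, ...)
  )
}
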