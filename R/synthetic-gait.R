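# Synthetic foot-IMU gait generator.
#
# Each swing is built from a smooth, twice-differentiable foot trajectory:
# minimum-jerk horizontal displacement along the current heading, a
# raised-cosine vertical lift, and a pitch profile that dips negative (toe
# down) at toe-off and rises positive before heel strike. The trajectory is
# converted *exactly* into sensor-frame signals: the accelerometer reads the
# specific force R'(a_g - g) and the gyroscope the body angular rate implied
# by the yaw/pitch time courses, so that an orientation filter plus
# zero-velocity-update integration can recover stride length and turning
# angle from first principles. A short decaying oscillation after each swing
# models the heel-strike impact transient seen in real foot-worn IMU data.

GRAVITY <- 9.80665

# Normalization of the pitch profile sin(x)(1-cos(x))/2 so that the
# `foot_lift_deg` parameter is the actual peak pitch magnitude.
PITCH_PEAK <- 0.6495191

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
min_jerk_acc <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3

pitch_profile <- function(tau) {
  x <- 2 * pi * tau
  -sin(x) * (1 - cos(x)) / 2 / PITCH_PEAK
}

#' Subject-level gait parameters
#'
#' @param stride_length_m normal stride length in metres.
#' @param cadence_hz stride cadence in strides per second (one stride per
#'   gait cycle of the instrumented foot).
#' @param foot_lift_deg peak foot-pitch magnitude during a normal swing,
#'   degrees (toe-up positive).
#' @param noise_sd_acc accelerometer white-noise SD, m/s^2.
#' @param noise_sd_gyr gyroscope white-noise SD, deg/s.
#' @return a list of class `subject_params`.
#' @export
subject_params <- function(stride_length_m = 1.2, cadence_hz = 1.0,
                           foot_lift_deg = 20, noise_sd_acc = 0.15,
                           noise_sd_gyr = 1.5) {
  if (stride_length_m <= 0) {
    stop_invalid("stride_length_m must be positive")
  }
  if (cadence_hz <= 0.1 || cadence_hz >= 3) {
    stop_invalid("cadence_hz must lie in (0.1, 3)")
  }
  structure(
    list(
      stride_length_m = stride_length_m, cadence_hz = cadence_hz,
      foot_lift_deg = foot_lift_deg, noise_sd_acc = noise_sd_acc,
      noise_sd_gyr = noise_sd_gyr
    ),
    class = "subject_params"
  )
}

#' Gait scenario segments
#'
#' A scenario is an ordered list of segments; each segment is either a
#' quiescent interval (`seg_rest()`, `seg_akinesia()`, `seg_sway()`) or a
#' sequence of strides (`seg_walk()`, `seg_shuffling()`, `seg_festination()`,
#' `seg_trembling()`, `seg_turn()`). FoG-subtype segments (shuffling,
#' festination, trembling, akinesia) are covered exactly by one annotated FoG
#' episode each.
#'
#' @param duration segment duration in seconds.
#' @param strides number of strides (annotated motion phases) in the segment.
#' @param angle_deg signed total turning angle of a turn segment, degrees.
#' @param bursts number of trembling heel-lift bursts.
#' @return a list describing one segment.
#' @name gait_segments
NULL

#' @rdname gait_segments
#' @export
seg_rest <- function(duration = 2) {
  list(kind = "rest", duration = duration)
}

#' @rdname gait_segments
#' @export
seg_walk <- function(strides = 10) {
  list(kind = "normal_walk", strides = strides)
}

#' @rdname gait_segments
#' @export
seg_shuffling <- function(strides = 5) {
  list(kind = "shuffling", strides = strides)
}

#' @rdname gait_segments
#' @export
seg_festination <- function(strides = 6) {
  list(kind = "festination", strides = strides)
}

#' @rdname gait_segments
#' @export
seg_trembling <- function(bursts = 4) {
  list(kind = "trembling", strides = bursts)
}

#' @rdname gait_segments
#' @export
seg_akinesia <- function(duration = 4) {
  list(kind = "akinesia", duration = duration)
}

#' @rdname gait_segments
#' @export
seg_turn <- function(angle_deg = 180, strides = NULL) {
  if (is.null(strides)) {
    strides <- max(1L, ceiling(abs(angle_deg) / 45))
  }
  list(kind = "turn", strides = strides, angle_deg = angle_deg)
}

#' @rdname gait_segments
#' @export
seg_sway <- function(duration = 2) {
  list(kind = "sway", duration = duration)
}

#' Assemble a gait scenario
#'
#' @param segments list of segments built with the `seg_*()` constructors.
#' @param subject a [subject_params()] object.
#' @param seed integer seed controlling sensor noise and gyro bias.
#' @return a list of class `gait_scenario`.
#' @export
gait_scenario <- function(segments, subject = subject_params(), seed = 1L) {
  if (!inherits(subject, "subject_params")) {
    subject <- do.call(subject_params, subject)
  }
  for (seg in segments) {
    if (!is.null(seg$duration) && seg$duration <= 0) {
      stop_invalid("segment durations must be positive")
    }
    if (!is.null(seg$strides) && seg$strides < 1) {
      stop_invalid("segments need at least one stride")
    }
  }
  structure(
    list(segments = segments, subject = subject, seed = as.integer(seed)),
    class = "gait_scenario"
  )
}

# Per-kind stride geometry. Shuffling keeps the foot nearly flat (< 5 deg
# lift, short strides); festination shrinks stride length geometrically
# (ratio 0.85) while the cycle shortens; trembling produces in-place 5 Hz
# heel-lift bursts; turns are pivot strides with per-stride yaw increments.
stride_plan <- function(seg, subject) {
  t_cycle <- 1 / subject$cadence_hz
  n <- seg$strides
  switch(seg$kind,
    normal_walk = tibble::tibble(
      length = rep(subject$stride_length_m, n),
      lift = rep(subject$foot_lift_deg, n),
      swing = rep(0.4 * t_cycle, n),
      gap = rep(0.6 * t_cycle, n),
      turn = 0, tremor = FALSE
    ),
    shuffling = tibble::tibble(
      length = rep(min(0.22, 0.2 * subject$stride_length_m / 1.2), n),
      lift = rep(4, n),
      swing = rep(0.3 * t_cycle, n),
      gap = rep(0.55 * t_cycle, n),
      turn = 0, tremor = FALSE
    ),
    festination = {
      k <- seq_len(n) - 1L
      tibble::tibble(
        length = pmax(0.08, 0.45 * subject$stride_length_m * 0.85^k),
        lift = pmax(4, 10 * 0.92^k),
        swing = pmax(0.16, 0.35 * t_cycle * 0.92^k),
        gap = pmax(0.3, 0.5 * t_cycle * 0.92^k),
        turn = 0, tremor = FALSE
      )
    },
    trembling = tibble::tibble(
      length = rep(0.02, n),
      lift = rep(8, n),
      swing = rep(0.35, n),
      gap = rep(0.45, n),
      turn = 0, tremor = TRUE
    ),
    turn = tibble::tibble(
      length = rep(0.15, n),
      lift = rep(12, n),
      swing = rep(0.45, n),
      gap = rep(0.65, n),
      turn = rep(seg$angle_deg / n, n),
      tremor = FALSE
    ),
    stop_invalid("no stride plan for segment kind ", seg$kind)
  )
}

fog_subtype_of <- c(
  shuffling = "shuffling", festination = "festination",
  trembling = "trembling", akinesia = "akinesia"
)

#' Generate a foot-IMU stream with ground truth
#'
#' Renders a [gait_scenario()] into a 200 Hz 6-axis inertial stream plus the
#' ground truth a clinical annotator would provide: motion phases (the swing
#' intervals, including shuffles and trembling heel lifts), FoG episodes
#' covering the FoG-subtype segments, and the true per-stride geometry.
#'
#' @param scenario a [gait_scenario()].
#' @param noise add sensor noise and a per-trial constant gyro bias
#'   (`FALSE` yields the noise-free kinematic signal).
#' @param keep_kinematics also return the per-sample true pitch/yaw and
#'   global acceleration used to synthesize the stream (for diagnostics).
#' @return a list with elements `stream` ([imu_stream()]), `truth` (list of
#'   `motion_phases`, `fog_episodes`, `per_stride`) and optionally
#'   `kinematics`.
#' @export
generate_gait <- function(scenario, noise = TRUE, keep_kinematics = FALSE) {
  if (!inherits(scenario, "gait_scenario")) {
    stop_invalid("generate_gait() needs a gait_scenario")
  }
  subject <- scenario$subject
  fs <- 200
  dt <- 1 / fs
  gap_between <- 0.5 # quiet stance inserted between segments

  # --- first pass: lay out segments and strides on the time axis ----------
  t_cursor <- 0
  seg_rows <- list()
  stride_rows <- list()
  for (si in seq_along(scenario$segments)) {
    seg <- scenario$segments[[si]]
    seg_start <- t_cursor
    if (seg$kind %in% c("rest", "akinesia", "sway")) {
      t_cursor <- t_cursor + seg$duration
    } else {
      plan <- stride_plan(seg, subject)
      for (k in seq_len(nrow(plan))) {
        sw_start <- t_cursor + plan$gap[k]
        sw_end <- sw_start + plan$swing[k]
        stride_rows[[length(stride_rows) + 1L]] <- tibble::tibble(
          segment = si, kind = seg$kind,
          start = sw_start, end = sw_end,
          true_stride_length_m = plan$length[k],
          true_turn_deg = plan$turn[k],
          true_duration_s = plan$swing[k],
          lift = plan$lift[k], tremor = plan$tremor[k]
        )
        t_cursor <- sw_end
      }
      t_cursor <- t_cursor + 0.3 # settle after the last swing
    }
    seg_rows[[si]] <- tibble::tibble(
      segment = si, kind = seg$kind, start = seg_start, end = t_cursor
    )
    t_cursor <- t_cursor + gap_between
  }
  segments <- dplyr::bind_rows(seg_rows)
  strides <- dplyr::bind_rows(stride_rows)
  if (nrow(strides) == 0L) {
    strides <- tibble::tibble(
      segment = integer(), kind = character(), start = numeric(),
      end = numeric(), true_stride_length_m = numeric(),
      true_turn_deg = numeric(), true_duration_s = numeric(),
      lift = numeric(), tremor = logical()
    )
  }
  total_t <- t_cursor
  n <- ceiling(total_t * fs) + 1L
  t <- (seq_len(n) - 1L) * dt

  # --- second pass: per-sample true pitch, yaw and global acceleration ----
  pitch <- numeric(n) # toe-up positive, degrees
  yaw <- numeric(n) # degrees
  acc_g <- matrix(0, n, 3) # global-frame linear acceleration, m/s^2
  yaw_cursor <- 0

  if (nrow(strides) > 0L) {
    for (k in seq_len(nrow(strides))) {
      st <- strides[k, ]
      idx <- which(t >= st$start & t < st$end)
      tau <- (t[idx] - st$start) / st$true_duration_s
      if (st$tremor) {
        # 5 Hz shank oscillation windowed over the burst, heel lift only
        w <- (1 - cos(2 * pi * tau)) / 2
        pitch[idx] <- st$lift * sin(2 * pi * 5 * (t[idx] - st$start)) * w
      } else {
        pitch[idx] <- st$lift * pitch_profile(tau)
      }
      heading <- (yaw_cursor + st$true_turn_deg / 2) * pi / 180
      u <- c(cos(heading), sin(heading))
      s_acc <- st$true_stride_length_m * min_jerk_acc(tau) /
        st$true_duration_s^2
      lift_m <- max(0.005, min(0.08, 0.05 * st$lift / 20))
      v_acc <- lift_m / 2 * (2 * pi / st$true_duration_s)^2 *
        cos(2 * pi * tau)
      acc_g[idx, 1] <- s_acc * u[1]
      acc_g[idx, 2] <- s_acc * u[2]
      acc_g[idx, 3] <- v_acc
      yaw[idx] <- yaw_cursor + st$true_turn_deg * min_jerk(tau)
      # heel-strike impact: decaying vertical oscillation after the swing
      imp_idx <- which(t >= st$end & t < st$end + 0.06)
      if (length(imp_idx) > 0L) {
        dt_imp <- t[imp_idx] - st$end
        amp <- max(1, min(8, 6 * st$lift / 20))
        acc_g[imp_idx, 3] <- acc_g[imp_idx, 3] +
          amp * sin(2 * pi * 40 * dt_imp) * exp(-dt_imp / 0.008)
      }
      yaw_cursor <- yaw_cursor + st$true_turn_deg
      # yaw holds its new value until the next stride
      after <- which(t >= st$end)
      yaw[after] <- yaw_cursor
    }
  }

  # postural sway segments (sit-to-stand and sitting down): unrest without
  # motion phases. The foot stays flat, so sway shows up as a yaw wobble
  # (weight shifting pivots the foot slightly) with a whisper of pitch --
  # enough rotational energy to leave rest, far below the motion thresholds
  sway_segs <- segments[segments$kind == "sway", ]
  if (nrow(sway_segs) > 0L) {
    for (k in seq_len(nrow(sway_segs))) {
      idx <- which(t >= sway_segs$start[k] & t < sway_segs$end[k])
      tr <- t[idx] - sway_segs$start[k]
      env <- sin(pi * tr / (sway_segs$end[k] - sway_segs$start[k]))^2
      yaw[idx] <- yaw[idx] + 6 * sin(2 * pi * 0.8 * tr) * env
      pitch[idx] <- pitch[idx] + 0.8 * sin(2 * pi * 0.6 * tr) * env
      acc_g[idx, 1] <- acc_g[idx, 1] + 0.3 * sin(2 * pi * 0.8 * tr) * env
    }
  }

  # --- convert the trajectory to exact sensor-frame signals ---------------
  beta <- -pitch * pi / 180 # internal rotation pitch (z-up, body->global)
  psi <- yaw * pi / 180
  d_beta <- c(0, diff(beta)) / dt
  d_psi <- c(0, diff(psi)) / dt
  # body rates for R = Rz(psi) Ry(beta): omega_b = (-psi' sin b, b', psi' cos b)
  gx <- (-d_psi * sin(beta)) * 180 / pi
  gy <- d_beta * 180 / pi
  gz <- (d_psi * cos(beta)) * 180 / pi
  # specific force f_b = R' (a_g + g_up)
  fx_g <- acc_g[, 1]
  fy_g <- acc_g[, 2]
  fz_g <- acc_g[, 3] + GRAVITY
  cb <- cos(beta)
  sb <- sin(beta)
  cp <- cos(psi)
  sp <- sin(psi)
  # Rz(-psi) then Ry(-beta)
  v1 <- cp * fx_g + sp * fy_g
  v2 <- -sp * fx_g + cp * fy_g
  ax <- cb * v1 - sb * fz_g
  ay <- v2
  az <- sb * v1 + cb * fz_g

  if (noise) {
    draws <- withr::with_seed(scenario$seed, {
      list(
        bias = stats::runif(3, -0.5, 0.5),
        acc = matrix(stats::rnorm(3 * n, 0, subject$noise_sd_acc), n, 3),
        gyr = matrix(stats::rnorm(3 * n, 0, subject$noise_sd_gyr), n, 3)
      )
    })
    ax <- ax + draws$acc[, 1]
    ay <- ay + draws$acc[, 2]
    az <- az + draws$acc[, 3]
    gx <- gx + draws$gyr[, 1] + draws$bias[1]
    gy <- gy + draws$gyr[, 2] + draws$bias[2]
    gz <- gz + draws$gyr[, 3] + draws$bias[3]
  }

  stream <- imu_stream(tibble::tibble(
    t = t, ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz
  ))

  mp <- strides[strides$kind != "akinesia", , drop = FALSE]
  truth_mp <- motion_phases(mp$start, mp$end, source = "annotated")
  fog_segs <- segments[segments$kind %in% names(fog_subtype_of), ,
    drop = FALSE
  ]
  truth_fog <- fog_episodes(
    fog_segs$start, fog_segs$end,
    subtype = unname(fog_subtype_of[fog_segs$kind])
  )
  out <- list(
    stream = stream,
    truth = list(
      motion_phases = truth_mp,
      fog_episodes = truth_fog,
      per_stride = dplyr::select(strides, -"lift", -"tremor"),
      segments = segments
    )
  )
  if (keep_kinematics) {
    out$kinematics <- tibble::tibble(
      t = t, pitch = pitch, yaw = yaw,
      agx = acc_g[, 1], agy = acc_g[, 2], agz = acc_g[, 3]
    )
  }
  out
}

#' Scripted test-protocol scenarios
#'
#' `protocol_10mwt()` scripts a 10 m walking test: walking ten metres,
#' turning around (180 degrees) and returning. `protocol_fac()` scripts a
#' freezing assessment course: standing up, walking one metre to a marked
#' square, turning 360 degrees in both directions, walking to a door,
#' pausing, returning and sitting down. Because freezing clusters at turns
#' and doorways, `fog_density` is the probability that a FoG segment (random
#' subtype) is inserted at each turn entry/exit or pause.
#'
#' @param subject a [subject_params()].
#' @param fog_density probability in \[0, 1\] of inserting a FoG segment at
#'   each provocation point.
#' @param seed integer seed (scenario structure and downstream noise).
#' @return a [gait_scenario()].
#' @export
protocol_10mwt <- function(subject = subject_params(), fog_density = 0,
                           seed = 1L) {
  if (fog_density < 0 || fog_density > 1) {
    stop_invalid("fog_density must be in [0, 1]")
  }
  n_walk <- ceiling(10 / subject$stride_length_m)
  segs <- withr::with_seed(seed, {
    segs <- list(seg_rest(2), seg_walk(n_walk))
    segs <- c(segs, maybe_fog_segment(fog_density))
    segs <- c(segs, list(seg_turn(180)))
    segs <- c(segs, maybe_fog_segment(fog_density))
    c(segs, list(seg_walk(n_walk), seg_rest(2)))
  })
  gait_scenario(segs, subject = subject, seed = seed)
}

#' @rdname protocol_10mwt
#' @export
protocol_fac <- function(subject = subject_params(), fog_density = 0,
                         seed = 1L) {
  if (fog_density < 0 || fog_density > 1) {
    stop_invalid("fog_density must be in [0, 1]")
  }
  n_1m <- ceiling(1 / subject$stride_length_m)
  n_3m <- ceiling(3 / subject$stride_length_m)
  n_4m <- ceiling(4 / subject$stride_length_m)
  segs <- withr::with_seed(seed, {
    segs <- list(seg_sway(2), seg_walk(n_1m))
    segs <- c(segs, maybe_fog_segment(fog_density))
    segs <- c(segs, list(seg_turn(360)))
    segs <- c(segs, maybe_fog_segment(fog_density))
    segs <- c(segs, list(seg_turn(-360), seg_walk(n_3m), seg_rest(1)))
    segs <- c(segs, maybe_fog_segment(fog_density))
    c(segs, list(seg_walk(n_4m), seg_sway(2)))
  })
  gait_scenario(segs, subject = subject, seed = seed)
}

maybe_fog_segment <- function(fog_density) {
  if (stats::runif(1) >= fog_density) {
    return(list())
  }
  switch(sample.int(3, 1),
    list(seg_shuffling(4)),
    list(seg_festination(5)),
    list(seg_trembling(3))
  )
}

# The standard ~60 s mixed trial used for cohort simulations: straight
# walking interleaved with one segment of each dynamic FoG subtype and a
# half turn.
default_trial_segments <- function() {
  list(
    seg_rest(1.5), seg_walk(8), seg_shuffling(5), seg_walk(6),
    seg_trembling(4), seg_walk(6), seg_turn(180), seg_festination(6),
    seg_walk(8), seg_rest(1.5)
  )
}

#' Simulate a multi-subject cohort
#'
#' Draws subject-level gait parameters once per subject (between-subject
#' variation) and renders `per_subject_trials` mixed walking trials per
#' subject with independent sensor noise, keeping subject ids for
#' leave-one-subject-out grouping. Each trial is the standard ~60 s mixed
#' scenario containing normal walking, shuffling, trembling, festination and
#' a half turn.
#'
#' @param n_subjects number of subjects (at least 2, else LOSO is undefined).
#' @param per_subject_trials trials per subject.
#' @param param_ranges named list of `c(min, max)` ranges for
#'   `stride_length_m`, `cadence_hz` and `foot_lift_deg`.
#' @param seed integer seed.
#' @return a tibble with columns `subject`, `trial`, `scenario`, `stream`,
#'   `truth` (the last three are list-columns).
#' @export
make_cohort <- function(n_subjects = 20, per_subject_trials = 1,
                        param_ranges = list(
                          stride_length_m = c(1.0, 1.4),
                          cadence_hz = c(0.8, 1.2),
                          foot_lift_deg = c(15, 25)
                        ),
                        seed = 1L) {
  if (n_subjects < 2) {
    stop_invalid("need at least 2 subjects for leave-one-subject-out")
  }
  setup <- withr::with_seed(seed, {
    subjects <- purrr::map(seq_len(n_subjects), function(i) {
      subject_params(
        stride_length_m = stats::runif(
          1, param_ranges$stride_length_m[1], param_ranges$stride_length_m[2]
        ),
        cadence_hz = stats::runif(
          1, param_ranges$cadence_hz[1], param_ranges$cadence_hz[2]
        ),
        foot_lift_deg = stats::runif(
          1, param_ranges$foot_lift_deg[1], param_ranges$foot_lift_deg[2]
        )
      )
    })
    trial_seeds <- matrix(
      sample.int(.Machine$integer.max, n_subjects * per_subject_trials),
      n_subjects, per_subject_trials
    )
    list(subjects = subjects, trial_seeds = trial_seeds)
  })
  rows <- list()
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(per_subject_trials)) {
      scen <- gait_scenario(
        default_trial_segments(),
        subject = setup$subjects[[i]],
        seed = setup$trial_seeds[i, j]
      )
      sim <- generate_gait(scen)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = sprintf("S%02d", i), trial = j,
        scenario = list(scen), stream = list(sim$stream),
        truth = list(sim$truth)
      )
    }
  }
  dplyr::bind_rows(rows)
}
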