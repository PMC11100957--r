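# Complementary-filter orientation estimation.
#
# Roll and pitch are propagated by gyro integration and corrected each sample
# toward the accelerometer inclination by a small gain; yaw comes from gyro
# integration alone (no magnetometer, so yaw is relative and drifts slowly).
# Pitch is reported toe-up positive. The filter is strictly causal and is the
# same code path for batch and streaming use.

orient_state_new <- function(gain = 0.02, sample_rate_hz = 200) {
  if (gain <= 0 || gain >= 1) {
    stop_invalid("orientation gain must lie in (0, 1)")
  }
  list(
    gain = gain, dt = 1 / sample_rate_hz,
    initialized = FALSE,
    roll = 0, beta = 0, psi = 0, # radians; beta is the internal rotation
    prev_g = c(0, 0, 0) # previous gyro sample, rad/s (trapezoid rule)
  )
}

# One filter update. acc in m/s^2 (sensor frame), gyr in deg/s.
# Returns list(state, out) where out carries euler angles (deg),
# quaternion, gravity-free global acceleration and global angular rate.
orient_step <- function(st, acc, gyr) {
  g_rad <- gyr * pi / 180
  anorm <- sqrt(sum(acc^2))
  if (!st$initialized) {
    if (anorm < 1) {
      stop_invalid(
        "degenerate inclination: acceleration norm too small to initialize"
      )
    }
    st$roll <- atan2(acc[2], acc[3])
    st$beta <- atan2(-acc[1], sqrt(acc[2]^2 + acc[3]^2))
    st$psi <- 0
    st$initialized <- TRUE
    st$prev_g <- g_rad
  } else {
    gm <- (g_rad + st$prev_g) / 2 # trapezoidal gyro integration
    st$prev_g <- g_rad
    sr <- sin(st$roll)
    cr <- cos(st$roll)
    cb <- cos(st$beta)
    tb <- sin(st$beta) / max(abs(cb), 1e-6) * sign(cb + (cb == 0))
    droll <- gm[1] + sr * tb * gm[2] + cr * tb * gm[3]
    dbeta <- cr * gm[2] - sr * gm[3]
    dpsi <- (sr * gm[2] + cr * gm[3]) / max(abs(cb), 1e-6) *
      sign(cb + (cb == 0))
    st$roll <- st$roll + droll * st$dt
    st$beta <- st$beta + dbeta * st$dt
    st$psi <- st$psi + dpsi * st$dt
    # trust the accelerometer inclination only in quasi-static moments,
    # when the specific-force norm is close to gravity; during dynamic
    # phases the gyro carries the orientation alone
    if (abs(anorm - GRAVITY) < 1.5) {
      roll_acc <- atan2(acc[2], acc[3])
      beta_acc <- atan2(-acc[1], sqrt(acc[2]^2 + acc[3]^2))
      st$roll <- st$roll + st$gain * (roll_acc - st$roll)
      st$beta <- st$beta + st$gain * (beta_acc - st$beta)
    }
  }
  sr <- sin(st$roll)
  cr <- cos(st$roll)
  sb <- sin(st$beta)
  cb <- cos(st$beta)
  sp <- sin(st$psi)
  cp <- cos(st$psi)
  # body->global rotation R = Rz(psi) Ry(beta) Rx(roll), z up
  r11 <- cp * cb
  r12 <- cp * sb * sr - sp * cr
  r13 <- cp * sb * cr + sp * sr
  r21 <- sp * cb
  r22 <- sp * sb * sr + cp * cr
  r23 <- sp * sb * cr - cp * sr
  r31 <- -sb
  r32 <- cb * sr
  r33 <- cb * cr
  acc_g <- c(
    r11 * acc[1] + r12 * acc[2] + r13 * acc[3],
    r21 * acc[1] + r22 * acc[2] + r23 * acc[3],
    r31 * acc[1] + r32 * acc[2] + r33 * acc[3] - GRAVITY
  )
  gyr_g <- c(
    r11 * gyr[1] + r12 * gyr[2] + r13 * gyr[3],
    r21 * gyr[1] + r22 * gyr[2] + r23 * gyr[3],
    r31 * gyr[1] + r32 * gyr[2] + r33 * gyr[3]
  )
  # quaternion (w, x, y, z) from ZYX angles
  hr <- st$roll / 2
  hb <- st$beta / 2
  hp <- st$psi / 2
  q <- c(
    cos(hr) * cos(hb) * cos(hp) + sin(hr) * sin(hb) * sin(hp),
    sin(hr) * cos(hb) * cos(hp) - cos(hr) * sin(hb) * sin(hp),
    cos(hr) * sin(hb) * cos(hp) + sin(hr) * cos(hb) * sin(hp),
    cos(hr) * cos(hb) * sin(hp) - sin(hr) * sin(hb) * cos(hp)
  )
  out <- c(
    st$roll * 180 / pi, -st$beta * 180 / pi, st$psi * 180 / pi,
    q, acc_g, gyr_g
  )
  list(state = st, out = out)
}

#' Estimate foot orientation from an IMU stream
#'
#' Runs a causal complementary filter: roll/pitch follow the gyroscope and
#' are pulled toward the accelerometer inclination with the given gain per
#' sample (time constant roughly `1 / (gain * sample_rate)` seconds); yaw is
#' gyro-integrated only. Returns per-sample Euler angles (degrees, pitch
#' toe-up positive), the unit orientation quaternion, gravity-removed global
#' acceleration (m/s^2) and global angular rate (deg/s).
#'
#' @param stream an [imu_stream()].
#' @param gain complementary-filter blending gain in (0, 1).
#' @return a tibble of class `fog_orientation` with columns `t`, `roll`,
#'   `pitch`, `yaw`, `qw`, `qx`, `qy`, `qz`, `agx`, `agy`, `agz`, `ggx`,
#'   `ggy`, `ggz`.
#' @export
estimate_orientation <- function(stream, gain = 0.02) {
  validate_imu_stream(stream)
  n <- nrow(stream)
  if (n == 0L) {
    stop_invalid("cannot estimate orientation of an empty stream")
  }
  if (stats::median(sqrt(stream$ax^2 + stream$ay^2 + stream$az^2)) < 1) {
    stop_invalid("degenerate inclination: acceleration stream is near zero")
  }
  st <- orient_state_new(gain, imu_meta(stream)$sample_rate_hz)
  acc <- cbind(stream$ax, stream$ay, stream$az)
  gyr <- cbind(stream$gx, stream$gy, stream$gz)
  out <- matrix(0, n, 13)
  for (i in seq_len(n)) {
    res <- orient_step(st, acc[i, ], gyr[i, ])
    st <- res$state
    out[i, ] <- res$out
  }
  res <- tibble::tibble(
    t = stream$t,
    roll = out[, 1], pitch = out[, 2], yaw = out[, 3],
    qw = out[, 4], qx = out[, 5], qy = out[, 6], qz = out[, 7],
    agx = out[, 8], agy = out[, 9], agz = out[, 10],
    ggx = out[, 11], ggy = out[, 12], ggz = out[, 13]
  )
  class(res) <- c("fog_orientation", class(res))
  attr(res, "gain") <- gain
  res
}
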