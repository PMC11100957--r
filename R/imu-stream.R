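#' Foot-mounted IMU streams
#'
#' An IMU stream is a tibble with one row per sample and columns `t` (seconds,
#' strictly increasing, nominally 200 Hz), `ax`, `ay`, `az` (linear
#' acceleration, m/s^2, sensor frame) and `gx`, `gy`, `gz` (angular rate,
#' degrees/s, sensor frame). Sensor metadata (sample rate, measurement ranges,
#' sensor id) travels in the `"meta"` attribute. The default sensor model is a
#' 200 Hz MEMS unit with a +/-16 g accelerometer and a +/-2000 deg/s gyroscope.
#'
#' @param data data frame with columns `t, ax, ay, az, gx, gy, gz`.
#' @param sample_rate_hz nominal sampling rate in Hz.
#' @param acc_range_g accelerometer full-scale range in g.
#' @param gyr_range_dps gyroscope full-scale range in degrees/s.
#' @param sensor_id free-text sensor identifier.
#' @return a tibble of class `imu_stream` with a `meta` attribute.
#' @export
#' @examples
#' s <- imu_stream(data.frame(
#'   t = c(0, 0.005, 0.01),
#'   ax = 0, ay = 0, az = 9.80665, gx = 0, gy = 0, gz = 0
#' ))
#' imu_meta(s)$sample_rate_hz
imu_stream <- function(data, sample_rate_hz = 200, acc_range_g = 16,
                       gyr_range_dps = 2000, sensor_id = "sim-foot") {
  cols <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop_invalid(
      "IMU stream is missing columns: ",
      paste(missing_cols, collapse = ", ")
    )
  }
  out <- tibble::as_tibble(data[cols])
  meta <- list(
    sample_rate_hz = sample_rate_hz,
    acc_range_g = acc_range_g,
    gyr_range_dps = gyr_range_dps,
    sensor_id = sensor_id
  )
  attr(out, "meta") <- meta
  class(out) <- c("imu_stream", class(tibble::tibble()))
  validate_imu_stream(out)
}

#' @rdname imu_stream
#' @param x an `imu_stream`.
#' @export
imu_meta <- function(x) {
  attr(x, "meta")
}

#' Validate an IMU stream against its sensor model
#'
#' Checks that timestamps are strictly increasing, that the median sample
#' interval agrees with the nominal rate within 1%, and that no sample exceeds
#' the stated accelerometer/gyroscope ranges.
#'
#' @param x an `imu_stream`.
#' @return `x`, invisibly unchanged, or a validation error.
#' @export
validate_imu_stream <- function(x) {
  meta <- imu_meta(x)
  if (is.null(meta)) {
    stop_invalid("IMU stream has no sensor metadata")
  }
  if (nrow(x) >= 2L) {
    dt <- diff(x$t)
    if (any(dt <= 0)) {
      stop_invalid("IMU timestamps must be strictly increasing")
    }
    nominal <- 1 / meta$sample_rate_hz
    if (abs(stats::median(dt) - nominal) >= 0.01 * nominal) {
      stop_invalid(
        "median sample interval deviates more than 1% from the nominal ",
        meta$sample_rate_hz, " Hz"
      )
    }
  }
  acc_max <- meta$acc_range_g * 9.80665
  if (nrow(x) > 0L) {
    if (max(abs(c(x$ax, x$ay, x$az))) > acc_max) {
      stop_invalid("acceleration exceeds the +/-", meta$acc_range_g, " g range")
    }
    if (max(abs(c(x$gx, x$gy, x$gz))) > meta$gyr_range_dps) {
      stop_invalid(
        "angular rate exceeds the +/-", meta$gyr_range_dps, " deg/s range"
      )
    }
  }
  x
}

#' Read and write IMU streams
#'
#' Streams are stored as plain CSV with a `#`-prefixed JSON metadata header
#' line, so fixtures stay diffable and carry their sensor model with them.
#' Units on disk are the package units: seconds, m/s^2, degrees/s.
#'
#' @param path file path.
#' @param format only `"csv"` is supported.
#' @return `read_imu_stream()` returns a validated [imu_stream()];
#'   `write_imu_stream()` returns `path` invisibly.
#' @export
read_imu_stream <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop_invalid("hdf5 streams are not supported by this build; use csv")
  }
  if (!file.exists(path)) {
    stop_invalid("no such file: ", path)
  }
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) {
    stop_invalid("stream file lacks the '#' JSON metadata header: ", path)
  }
  meta <- jsonlite::fromJSON(sub("^#\\s*", "", header))
  data <- utils::read.csv(path, comment.char = "#")
  imu_stream(
    data,
    sample_rate_hz = meta$sample_rate_hz,
    acc_range_g = meta$acc_range_g,
    gyr_range_dps = meta$gyr_range_dps,
    sensor_id = meta$sensor_id %||% "unknown"
  )
}

#' @rdname read_imu_stream
#' @param x an `imu_stream`.
#' @export
write_imu_stream <- function(x, path) {
  validate_imu_stream(x)
  header <- paste0(
    "# ",
    jsonlite::toJSON(imu_meta(x), auto_unbox = TRUE, digits = NA)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @export
print.imu_stream <- function(x, ...) {
  meta <- imu_meta(x)
  cat(sprintf(
    "<imu_stream> %d samples @ %g Hz (+/-%g g, +/-%g deg/s), %.2f s\n",
    nrow(x), meta$sample_rate_hz, meta$acc_range_g, meta$gyr_range_dps,
    if (nrow(x)) diff(range(x$t)) else 0
  ))
  NextMethod()
}
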