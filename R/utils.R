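# Small shared helpers: interval algebra on half-open intervals, printed-rate
# rounding, millisecond quantization, rank AUC.

#' Round half-up to a fixed number of decimals
#'
#' Printed percentages in gait reports use commercial (half-up) rounding, so
#' `round_half_up(94.05, 1)` is 94.1 regardless of binary representation.
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Quantize times to the controller clock
#'
#' Sensor and stimulator share one session clock synchronized to 1 ms; event
#' timestamps are snapped to that grid before the cueing controller sees them.
#'
#' @param t numeric vector of times in seconds.
#' @param resolution clock resolution in seconds (default 1 ms).
#' @return quantized times.
#' @export
quantize_time <- function(t, resolution = 0.001) {
  floor(t / resolution + 0.5 + sqrt(.Machine$double.eps)) * resolution
}

# Half-open interval [start, end) overlap: a shared endpoint is not an overlap.
intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  (a_start < b_end) & (b_start < a_end)
}

# Total measure of a union of possibly-overlapping intervals.
interval_union_length <- function(start, end) {
  if (length(start) == 0L) {
    return(0)
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  total <- 0
  cur_s <- start[1L]
  cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]
      cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  total + (cur_e - cur_s)
}

# Normalize a set of intervals to a disjoint, sorted union.
interval_union <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  us <- start[1L]
  ue <- end[1L]
  out_s <- numeric()
  out_e <- numeric()
  for (i in seq_along(start)[-1L]) {
    if (start[i] > ue) {
      out_s <- c(out_s, us)
      out_e <- c(out_e, ue)
      us <- start[i]
      ue <- end[i]
    } else {
      ue <- max(ue, end[i])
    }
  }
  tibble::tibble(start = c(out_s, us), end = c(out_e, ue))
}

# Measure of the intersection of two disjoint interval sets.
interval_intersection_length <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(0)
  }
  total <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start[i], b$start)
    hi <- pmin(a$end[i], b$end)
    total <- total + sum(pmax(hi - lo, 0))
  }
  total
}

# Intersection of a disjoint interval set with one window [lo, hi).
interval_clip <- function(x, lo, hi) {
  s <- pmax(x$start, lo)
  e <- pmin(x$end, hi)
  keep <- e > s
  tibble::tibble(start = s[keep], end = e[keep])
}

# Rank-statistic AUC for a binary outcome; positive class given explicitly.
# Ties in score get average ranks (equivalent to the trapezoidal ROC area).
rank_auc <- function(score, truth, positive) {
  pos <- truth == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Validation error helper: all user-facing validation failures share a class
# so callers (and the CLI) can map them to exit code 2.
stop_invalid <- function(...) {
  msg <- paste0(...)
  rlang::abort(msg, class = "gaitcue_validation_error")
}

`%||%` <- rlang::`%||%`
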