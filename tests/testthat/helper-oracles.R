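# Independent oracles used across the suite. These deliberately use
# different machinery from the package code paths: integer-millisecond
# timeline walking for the cueing controller, exhaustive stump enumeration
# for the boosting recursion, and 1 ms rasterization for interval measures.

# ---- brute-force cueing controller on an integer 1 ms timeline -----------
oracle_session <- function(events, config) {
  to_ms <- function(x) as.integer(round(x * 1000))
  t_on <- to_ms(config$t_agsc_on)
  t_off <- to_ms(config$t_off)
  t_min <- to_ms(config$t_min)
  t_max <- to_ms(config$t_max)
  if (nrow(events) == 0L) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  et <- to_ms(events$time + config$event_latency)
  o <- order(et, match(events$kind, c("motion_end", "motion_start")))
  ek <- events$kind[o]
  ec <- events$class_label[o]
  et <- et[o]
  horizon <- max(et) + t_max + 1L
  starts <- integer()
  ends <- integer()
  last_end <- -.Machine$integer.max
  open_start <- NA_integer_
  cur_cued <- FALSE
  interval_end <- -.Machine$integer.max
  evi <- 1L
  n_ev <- length(et)
  for (tm in seq.int(min(et), horizon)) {
    if (!is.na(open_start) && tm == open_start + t_max) {
      starts <- c(starts, open_start)
      ends <- c(ends, tm)
      last_end <- tm
      open_start <- NA_integer_
    }
    while (evi <= n_ev && et[evi] == tm) {
      if (ek[evi] == "motion_start") {
        cur_cued <- FALSE
        if (tm < interval_end && tm >= last_end + t_off) {
          open_start <- tm
          cur_cued <- TRUE
        }
      } else {
        if (!is.na(open_start)) {
          e <- min(max(open_start + t_min, tm), open_start + t_max)
          starts <- c(starts, open_start)
          ends <- c(ends, e)
          last_end <- e
          open_start <- NA_integer_
        }
        if (identical(ec[evi], "fog")) {
          interval_end <- max(interval_end, tm + t_on)
          if (config$cue_trigger_phase && !cur_cued &&
            tm >= last_end + t_off) {
            starts <- c(starts, tm)
            ends <- c(ends, tm + t_min)
            last_end <- tm + t_min
            cur_cued <- TRUE
          }
        }
      }
      evi <- evi + 1L
    }
  }
  if (!is.na(open_start)) {
    starts <- c(starts, open_start)
    ends <- c(ends, open_start + t_max)
  }
  tibble::tibble(start = starts / 1000, end = ends / 1000)
}

# random motion-event streams exercising t_min / t_max / t_off edge cases
random_event_stream <- function(seed, duration = 8) {
  withr::with_seed(seed, {
    t <- stats::runif(1, 0.1, 0.5)
    rows <- list()
    while (t < duration) {
      gap <- stats::runif(1, 0.02, 1.2)
      dur <- stats::runif(1, 0.03, 1.1)
      cls <- sample(c("fog", "normal"), 1, prob = c(0.4, 0.6))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = c("motion_start", "motion_end"),
        time = c(t, t + dur),
        class_label = c("none", cls)
      )
      t <- t + dur + gap
    }
    dplyr::bind_rows(rows)
  })
}

# ---- exhaustive stump-enumeration SAMME boosting -------------------------
oracle_adaboost <- function(x, labels, n_rounds) {
  y_pos <- labels == "fog"
  n <- nrow(x)
  w <- rep(1 / n, n)
  gini2 <- function(wp, wn) {
    tot <- wp + wn
    if (tot <= 0) {
      return(0)
    }
    tot * (1 - (wp / tot)^2 - (wn / tot)^2)
  }
  stumps <- list()
  alphas <- numeric()
  for (m in seq_len(n_rounds)) {
    parent <- gini2(sum(w[y_pos]), sum(w[!y_pos]))
    best <- NULL
    for (j in seq_len(ncol(x))) {
      xs <- sort(unique(x[, j]))
      if (length(xs) < 2L) next
      for (thr in (xs[-1] + xs[-length(xs)]) / 2) {
        left <- x[, j] <= thr
        g <- gini2(sum(w[left & y_pos]), sum(w[left & !y_pos])) +
          gini2(sum(w[!left & y_pos]), sum(w[!left & !y_pos]))
        if (is.null(best) || g < best$g - 1e-12) {
          best <- list(j = j, thr = thr, g = g)
        }
      }
    }
    maj <- function(idx) {
      if (sum(w[idx & y_pos]) > sum(w[idx & !y_pos])) "fog" else "normal"
    }
    if (is.null(best) || best$g >= parent - 1e-12 ||
      all(y_pos) || !any(y_pos)) {
      pred <- rep(maj(rep(TRUE, n)), n)
      stump <- list(leaf = pred[1])
    } else {
      left <- x[, best$j] <= best$thr
      stump <- list(
        j = best$j, thr = best$thr,
        left_lab = maj(left), right_lab = maj(!left)
      )
      pred <- ifelse(left, stump$left_lab, stump$right_lab)
    }
    mis <- pred != labels
    err <- sum(w[mis]) / sum(w)
    if (err <= 0) {
      stumps[[length(stumps) + 1L]] <- stump
      alphas <- c(alphas, log((1 - 1e-10) / 1e-10))
      break
    }
    if (err >= 0.5) {
      break
    }
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

oracle_adaboost_predict <- function(model, x) {
  n <- nrow(x)
  vote <- rep(0, n)
  for (m in seq_along(model$stumps)) {
    s <- model$stumps[[m]]
    pred <- if (!is.null(s$leaf)) {
      rep(s$leaf, n)
    } else {
      ifelse(x[, s$j] <= s$thr, s$left_lab, s$right_lab)
    }
    vote <- vote + model$alphas[m] * (pred == "fog")
  }
  score <- vote / sum(model$alphas)
  list(label = ifelse(score > 0.5, "fog", "normal"), score = score)
}

# ---- 1 ms rasterized coverage oracle -------------------------------------
raster_coverage <- function(mps, trains, intervals, horizon) {
  grid <- seq(0, horizon, by = 0.001)
  inside <- function(tbl) {
    out <- rep(FALSE, length(grid))
    for (i in seq_len(nrow(tbl))) {
      out <- out | (grid >= tbl$start[i] & grid < tbl$end[i])
    }
    out
  }
  iv <- inside(intervals)
  mp <- inside(mps) & iv
  st <- inside(trains) & iv
  nonmp <- iv & !mp
  list(
    pct_mp = if (sum(mp) > 0) 100 * sum(st & mp) / sum(mp) else NA_real_,
    pct_nonmp = if (sum(nonmp) > 0) {
      100 * sum(st & nonmp) / sum(nonmp)
    } else {
      NA_real_
    }
  )
}

# random non-overlapping interval sets
random_intervals <- function(n, seed, gap_max = 1, dur_max = 0.8) {
  withr::with_seed(seed, {
    gaps <- stats::runif(n, 0.01, gap_max)
    durs <- stats::runif(n, 0.02, dur_max)
    starts <- cumsum(gaps + c(0, durs[-n]))
    tibble::tibble(start = starts, end = starts + durs)
  })
}

# fixtures with prescribed matching structure: n_correct annotated phases
# each overlapped by one detected phase, n_missed annotated with none, and
# n_false detected phases overlapping nothing
build_match_fixture <- function(n_correct, n_missed, n_false) {
  n_a <- n_correct + n_missed
  a_start <- seq_len(n_a) * 2
  annotated <- tibble::tibble(start = a_start, end = a_start + 0.5)
  d_start <- a_start[seq_len(n_correct)] + 0.1
  detected <- tibble::tibble(start = d_start, end = d_start + 0.45)
  if (n_false > 0) {
    f_start <- max(annotated$end) + 2 + seq_len(n_false) * 2
    detected <- rbind(
      detected, tibble::tibble(start = f_start, end = f_start + 0.3)
    )
  }
  list(annotated = annotated, detected = detected)
}
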