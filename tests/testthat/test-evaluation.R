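test_that("overlap matching follows the exclusive-overlap rule", {
  annotated <- motion_phases(c(1, 3), c(2, 4))
  detected <- tibble::tibble(
    start = c(1.5, 1.9, 3.1), end = c(2.5, 3.2, 3.9)
  )
  m <- match_phases(annotated, detected)
  expect_equal(m$counts$n_correct, 2)
  expect_equal(m$counts$n_missed, 0)
  expect_equal(m$counts$n_false, 1) # (1.9, 3.2) spans both annotated phases
  expect_equal(m$false_detections$start, 1.9)

  # perfect detection
  m2 <- match_phases(annotated, annotated)
  expect_equal(m2$counts$n_correct, 2)
  expect_equal(m2$counts$n_false, 0)
  expect_true(all(delay_stats(m2)$samples == 0))

  # nothing detected
  m3 <- match_phases(annotated, motion_phases())
  expect_equal(m3$counts$n_missed, 2)
  expect_equal(m3$rates$rate_missed, 100)

  # a shared endpoint is not an overlap (half-open intervals)
  m4 <- match_phases(
    motion_phases(1, 2), motion_phases(2, 3, source = "detected")
  )
  expect_equal(m4$counts$n_correct, 0)
  expect_equal(m4$counts$n_false, 1)

  expect_error(
    match_phases(tibble::tibble(start = c(1, 1.5), end = c(2, 2.5)),
      detected
    ),
    class = "gaitcue_validation_error"
  )
})

test_that("among several exclusive detections only the first counts", {
  annotated <- motion_phases(0, 2)
  detected <- motion_phases(c(0.2, 1.2), c(0.8, 1.8), source = "detected")
  m <- match_phases(annotated, detected)
  expect_equal(m$counts$n_correct, 1)
  expect_equal(m$pairs$d_start, 0.2)
  expect_equal(m$counts$n_false, 0) # the second exclusive one is neglected
})

test_that("matching equals a naive per-pair intersection oracle", {
  for (seed in 1:300) {
    sets <- withr::with_seed(seed, {
      na <- sample(1:8, 1)
      nd <- sample(0:8, 1)
      list(
        a = random_intervals(na, seed = seed * 2 + 1),
        d = if (nd > 0) random_intervals(nd, seed = seed * 2) else
          tibble::tibble(start = numeric(), end = numeric())
      )
    })
    m <- match_phases(sets$a, sets$d)
    # naive oracle: per-pair positive intersection length
    inter <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))
    n_ov <- integer(nrow(sets$d))
    which_a <- integer(nrow(sets$d))
    for (j in seq_len(nrow(sets$d))) {
      ov <- vapply(seq_len(nrow(sets$a)), function(i) {
        inter(
          sets$a$start[i], sets$a$end[i], sets$d$start[j], sets$d$end[j]
        ) > 0
      }, TRUE)
      n_ov[j] <- sum(ov)
      which_a[j] <- if (sum(ov) == 1) which(ov) else NA_integer_
    }
    correct <- 0L
    for (i in seq_len(nrow(sets$a))) {
      if (any(which_a == i & n_ov == 1, na.rm = TRUE)) correct <- correct + 1L
    }
    expect_equal(m$counts$n_correct, correct)
    expect_equal(m$counts$n_false, sum(n_ov != 1))
  }
})

test_that("delay statistics are plain differences with medians", {
  m <- match_phases(
    motion_phases(1.0, 2.0),
    motion_phases(1.05, 2.01, source = "detected")
  )
  d <- delay_stats(m)
  expect_equal(d$samples$start_delay, 0.05)
  expect_equal(d$samples$end_delay, 0.01)
  expect_equal(d$samples$duration_diff, -0.04)

  m2 <- match_phases(
    motion_phases(c(1, 3), c(2, 4)),
    motion_phases(c(1.02, 3.08), c(2, 4), source = "detected")
  )
  d2 <- delay_stats(m2)
  expect_equal(
    d2$summary$median[d2$summary$measure == "start_delay"], 0.05
  )
})

test_that("cueing coverage is exact on constructed sessions", {
  mps <- motion_phases(c(0, 2), c(0.5, 2.5))
  intervals <- tibble::tibble(start = 0, end = 3)
  # trains exactly equal to the MPs -> 100% MP coverage, 0% non-MP
  cov <- cueing_coverage(mps, tibble::tibble(start = c(0, 2), end = c(0.5, 2.5)), intervals)
  expect_equal(cov$pct_mp_time_stimulated, 100)
  expect_equal(cov$pct_nonmp_time_stimulated, 0)
  # a train covering MP (0, 0.5) and as much non-MP inside (0, 1)
  cov2 <- cueing_coverage(
    motion_phases(0, 0.5),
    tibble::tibble(start = 0, end = 1),
    tibble::tibble(start = 0, end = 1)
  )
  expect_equal(cov2$pct_mp_time_stimulated, 100)
  expect_equal(cov2$pct_nonmp_time_stimulated, 100)
  # zero MP time inside the intervals -> undefined
  cov3 <- cueing_coverage(
    motion_phases(10, 11),
    tibble::tibble(start = 0, end = 1),
    tibble::tibble(start = 0, end = 1)
  )
  expect_true(is.na(cov3$pct_mp_time_stimulated))
})

test_that("coverage agrees with a 1 ms rasterized oracle on random sessions", {
  quantize_tbl <- function(x) {
    tibble::tibble(
      start = quantize_time(x$start), end = quantize_time(x$end)
    )
  }
  for (seed in 1:25) {
    mps <- quantize_tbl(random_intervals(6, seed = seed))
    trains <- quantize_tbl(random_intervals(5, seed = seed + 1000))
    intervals <- quantize_tbl(random_intervals(2, seed = seed + 2000,
      gap_max = 3, dur_max = 4
    ))
    cov <- cueing_coverage(mps, trains, intervals)
    ras <- raster_coverage(
      mps, trains, intervals,
      horizon = max(mps$end, trains$end, intervals$end) + 0.01
    )
    if (!is.na(cov$pct_mp_time_stimulated)) {
      expect_lt(abs(cov$pct_mp_time_stimulated - ras$pct_mp), 0.1)
    }
    if (!is.na(cov$pct_nonmp_time_stimulated) && !is.na(ras$pct_nonmp)) {
      expect_lt(abs(cov$pct_nonmp_time_stimulated - ras$pct_nonmp), 0.1)
    }
  }
})

test_that("FoG labelling uses the end-time membership rule", {
  episodes <- fog_episodes(c(2, 6), c(4, 8), subtype = "shuffling")
  detected <- motion_phases(
    c(1.0, 3.0, 3.5, 7.9), c(2.5, 3.5, 4.5, 8.5),
    source = "detected"
  )
  lab <- label_detected(detected, episodes)
  # ends at 2.5 (inside), 3.5 (inside), 4.5 (outside: overlaps but ends
  # after the episode), 8.5 (outside)
  expect_equal(lab, c("fog", "fog", "normal", "normal"))
  # inclusive start, exclusive end
  lab2 <- label_detected(
    motion_phases(c(1.5, 3.5), c(2.0, 4.0), source = "detected"), episodes
  )
  expect_equal(lab2, c("fog", "normal"))

  # random phases against a brute-force membership loop
  for (seed in 1:20) {
    ph <- random_intervals(20, seed = seed)
    ep <- random_intervals(4, seed = seed + 50, gap_max = 3, dur_max = 2)
    got <- label_detected(ph, ep)
    want <- vapply(ph$end, function(e) {
      hit <- FALSE
      for (i in seq_len(nrow(ep))) {
        if (e >= ep$start[i] && e < ep$end[i]) hit <- TRUE
      }
      if (hit) "fog" else "normal"
    }, "")
    expect_equal(got, want)
  }
})

test_that("classification metrics match hand arithmetic", {
  perfect <- classification_metrics(
    c("fog", "normal"), c("fog", "normal")
  )
  expect_equal(unname(perfect$total), c(100, 100, 100))

  pred <- c(rep("fog", 8), rep("normal", 2), rep("normal", 6), rep("fog", 4))
  truth <- c(rep("fog", 10), rep("normal", 10))
  m <- classification_metrics(pred, truth)
  expect_equal(m$total[["sensitivity"]], 80)
  expect_equal(m$total[["specificity"]], 60)
  expect_equal(m$total[["accuracy"]], 70)
  expect_equal(unname(m$confusion), c(8, 2, 6, 4))

  allnorm <- classification_metrics(
    rep("normal", 4), c("fog", "fog", "normal", "normal")
  )
  expect_equal(allnorm$total[["sensitivity"]], 0)
  expect_error(
    classification_metrics(character(), character()),
    class = "gaitcue_validation_error"
  )
})

test_that("gait reports count phases, FoG phases and cued phases", {
  phases <- dplyr::mutate(
    motion_phases(
      seq(1, 19, by = 2), seq(1.4, 19.4, by = 2),
      source = "detected"
    ),
    class_label = rep(c("fog", "normal", "normal", "normal", "normal"), 2)
  )
  trains <- tibble::tibble(
    start = phases$start[1:5] + 0.05, end = phases$start[1:5] + 0.3
  )
  session <- list(
    duration_s = 20, phases = phases, trains = trains,
    config = cueing_config()
  )
  rep_ <- gait_report(session)
  expect_equal(rep_$n_mps, 10)
  expect_equal(rep_$n_fog_mps, 2)
  expect_equal(rep_$n_cued_mps, 5)
  expect_equal(rep_$cueing_s, 5 * 0.25)
  expect_equal(rep_$percent_cueing_active, round_half_up(100 * 1.25 / 20, 1))

  empty <- gait_report(list(
    duration_s = 0, phases = dplyr::mutate(motion_phases(), score = 1)[0, ],
    trains = tibble::tibble(start = numeric(), end = numeric()),
    config = cueing_config()
  ))
  expect_equal(empty$n_mps, 0)
  expect_equal(empty$percent_cueing_active, 0)
})

test_that("report arithmetic averages cueing shares per subject then overall", {
  courses <- tibble::tibble(
    subject = c("SC", "SC", "CS", "CS"),
    duration_s = c(116.4, 183.7, 77.1, 86.5),
    cueing_s = c(43.9, 155.9, 23.7, 49.4)
  )
  s <- cueing_active_summary(courses)
  expect_equal(sort(s$per_subject$percent_cueing_active), c(43.9, 61.3))
  expect_equal(s$overall, 52.6)
})
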