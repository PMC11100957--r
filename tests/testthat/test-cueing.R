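ev <- function(kind, time, class_label = "none") {
  tibble::tibble(kind = kind, time = time, class_label = class_label)
}

cfg0 <- cueing_config(event_latency = 0)

test_that("all-normal sessions emit no trains", {
  events <- rbind(
    ev("motion_start", 1), ev("motion_end", 1.4, "normal"),
    ev("motion_start", 2), ev("motion_end", 2.4, "normal")
  )
  s <- run_session(events, cfg0)
  expect_equal(nrow(s$trains), 0)
  expect_equal(nrow(s$intervals), 0)
  empty <- run_session(ev("motion_start", numeric(0)), cfg0)
  expect_equal(nrow(empty$trains), 0)
})

test_that("train durations are clamped into [t_min, t_max]", {
  base <- rbind(
    ev("motion_start", 0.8), ev("motion_end", 1.0, "fog")
  )
  # MP of 0.5 s inside the interval -> train of exactly 0.5 s
  s_a <- run_session(
    rbind(base, ev("motion_start", 2), ev("motion_end", 2.5, "normal")),
    cfg0
  )
  expect_equal(
    s_a$trains$end[2] - s_a$trains$start[2], 0.5
  )
  # MP of 0.10 s -> train lengthened to exactly t_min = 0.2 s
  s_b <- run_session(
    rbind(base, ev("motion_start", 2), ev("motion_end", 2.1, "normal")),
    cfg0
  )
  expect_equal(s_b$trains$end[2] - s_b$trains$start[2], 0.2)
  # MP of 0.9 s -> train capped at exactly t_max = 0.8 s
  s_c <- run_session(
    rbind(base, ev("motion_start", 2), ev("motion_end", 2.9, "normal")),
    cfg0
  )
  expect_equal(s_c$trains$end[2] - s_c$trains$start[2], 0.8)
})

test_that("FoG phases open and extend the presumed-episode interval", {
  events <- rbind(
    ev("motion_start", 0.9), ev("motion_end", 1.0, "fog"),
    ev("motion_start", 3.8), ev("motion_end", 4.0, "fog"),
    ev("motion_start", 8.5), ev("motion_end", 8.8, "normal"),
    ev("motion_start", 9.5), ev("motion_end", 9.8, "normal")
  )
  s <- run_session(events, cfg0)
  expect_equal(nrow(s$intervals), 1)
  expect_equal(s$intervals$start, 1.0)
  expect_equal(s$intervals$end, 9.0) # extended by the fog MP ending at 4.0
  # the MP starting at 8.5 (inside) is cued; the one at 9.5 (outside) is not
  expect_true(any(abs(s$trains$start - 8.5) < 1e-9))
  expect_false(any(s$trains$start > 9.2))
})

test_that("the t_off pause suppresses closely following trains", {
  events <- rbind(
    ev("motion_start", 0.5), ev("motion_end", 0.7, "fog"),
    ev("motion_start", 1.0), ev("motion_end", 1.2, "normal"),
    ev("motion_start", 1.25), ev("motion_end", 1.5, "normal")
  )
  s <- run_session(events, cfg0)
  expect_equal(nrow(s$trains), 2)
  expect_false(any(abs(s$trains$start - 1.25) < 1e-9))
})

test_that("the interval-opening phase is cued retroactively unless disabled", {
  events <- rbind(
    ev("motion_start", 0.8), ev("motion_end", 1.0, "fog")
  )
  s <- run_session(events, cfg0)
  expect_equal(s$trains$start, 1.0)
  expect_equal(s$trains$end, 1.2)
  no_retro <- cueing_config(event_latency = 0, cue_trigger_phase = FALSE)
  s2 <- run_session(events, no_retro)
  expect_equal(nrow(s2$trains), 0)
  expect_equal(nrow(s2$intervals), 1)
})

test_that("event latency shifts and quantizes controller times", {
  cfg <- cueing_config(event_latency = 0.0075)
  events <- rbind(
    ev("motion_start", 0.8), ev("motion_end", 1.0, "fog")
  )
  s <- run_session(events, cfg)
  expect_equal(s$trains$start, 1.008)
  expect_equal(s$intervals$start, 1.008)
})

test_that("non-monotone events are rejected", {
  st <- cueing_state()
  st <- on_event(st, list(kind = "motion_start", time = 2), cfg0)
  expect_error(
    on_event(st, list(kind = "motion_start", time = 1), cfg0),
    class = "gaitcue_validation_error"
  )
})

test_that("controller equals the 1 ms brute-force timeline on random streams", {
  n_bad <- 0
  for (seed in 1:200) {
    events <- random_event_stream(seed, duration = 6)
    s <- run_session(events, cueing_config())
    o <- oracle_session(events, cueing_config())
    same <- isTRUE(all.equal(
      round(as.matrix(s$trains[c("start", "end")]) * 1000),
      round(as.matrix(o) * 1000),
      check.attributes = FALSE
    ))
    if (!same) n_bad <- n_bad + 1
    # invariants on every train
    cfg <- cueing_config()
    if (nrow(s$trains) > 0) {
      durs <- s$trains$end - s$trains$start
      expect_true(all(durs >= cfg$t_min - 1e-9))
      expect_true(all(durs <= cfg$t_max + 1e-9))
      gaps <- s$trains$start[-1] - s$trains$end[-nrow(s$trains)]
      expect_true(all(gaps >= cfg$t_off - 1e-9))
      # no train outside [first fog classification, last interval end]
      expect_true(all(s$trains$start >= min(s$intervals$start) - 1e-9))
      expect_true(all(s$trains$start <= max(s$intervals$end) + 1e-9))
    }
  }
  expect_equal(n_bad, 0)
})

test_that("rhythmic cueing schedules periodic trains", {
  trains <- rhythmic_cueing(0, 5, period = 1, duty = 0.3)
  expect_equal(nrow(trains), 5)
  expect_equal(trains$start, 0:4)
  expect_equal(trains$end - trains$start, rep(0.3, 5))
  expect_equal(unique(trains$trigger), "rhythmic")

  expect_warning(
    short <- rhythmic_cueing(0, 3, period = 1, duty = 0.1),
    "lengthened"
  )
  expect_equal(short$end - short$start, rep(0.2, 3))

  expect_equal(nrow(rhythmic_cueing(5, 5, period = 1, duty = 0.3)), 0)
  expect_error(
    rhythmic_cueing(0, 5, period = 1, duty = 1.2),
    class = "gaitcue_validation_error"
  )
})
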